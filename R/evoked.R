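## Count spikes of a sorted spike train in [t + lo, t + hi) around each
## event time t. `left.open` makes findInterval count spikes strictly
## below each edge, which yields half-open [lo, hi) windows.
window_counts <- function(spikes, event_times, lo, hi) {
  if (length(event_times) == 0) return(integer(0))
  edges <- as.vector(rbind(event_times + lo, event_times + hi))
  idx <- findInterval(edges, spikes, left.open = TRUE)
  idx[seq(2, length(idx), by = 2)] - idx[seq(1, length(idx), by = 2)]
}

#' Peri-stimulus time histogram
#'
#' Bins spikes relative to each event with half-open bins `[lo, hi)`.
#'
#' @param spikes sorted numeric vector of spike times (s).
#' @param event_times event onsets (s).
#' @param window two numbers, window relative to the event (s); must be an
#'   exact multiple of `bin_width` wide.
#' @param bin_width bin width in seconds.
#' @return list of class `ss_psth`: `bin_edges` (s, length bins + 1),
#'   `counts` (trials x bins matrix), `rate` (Hz per bin, averaged over
#'   trials), `n_trials`.
#' @export
compute_psth <- function(spikes, event_times, window = c(-0.2, 0.1),
                         bin_width = 0.005) {
  stopifnot(bin_width > 0, length(window) == 2, window[2] > window[1])
  n_bins <- (window[2] - window[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    stop("`window` must span an integer number of bins", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  if (length(event_times) == 0) {
    stop("cannot compute a PSTH with no events", call. = FALSE)
  }
  spikes <- sort(spikes)
  edges <- window[1] + bin_width * (0:n_bins)
  counts <- matrix(0L, nrow = length(event_times), ncol = n_bins)
  for (j in seq_len(n_bins)) {
    counts[, j] <- window_counts(spikes, event_times, edges[j], edges[j + 1])
  }
  structure(list(bin_edges = edges, counts = counts,
                 rate = colMeans(counts) / bin_width,
                 n_trials = length(event_times)),
            class = "ss_psth")
}

#' Evoked-response amplitude of a PSTH
#'
#' Mean firing rate in the response window (10--50 ms after the event)
#' minus the mean rate in the baseline window (200--0 ms before it).
#'
#' @param psth an `ss_psth` covering at least `[-0.2, 0.05]` s.
#' @param response_window,baseline_window windows in seconds.
#' @return amplitude in Hz.
#' @export
response_amplitude <- function(psth, response_window = c(0.01, 0.05),
                               baseline_window = c(-0.2, 0)) {
  e <- psth$bin_edges
  bw <- e[2] - e[1]
  mids <- e[-length(e)] + bw / 2
  in_resp <- mids > response_window[1] & mids < response_window[2]
  in_base <- mids > baseline_window[1] & mids < baseline_window[2]
  if (!any(in_resp) || !any(in_base)) {
    stop("PSTH does not cover the response and baseline windows",
         call. = FALSE)
  }
  mean(psth$rate[in_resp]) - mean(psth$rate[in_base])
}

#' Per-event evoked amplitudes
#'
#' One amplitude per event: the rate in 10--50 ms after the event minus
#' that event's own 0--200 ms baseline rate.
#'
#' @inheritParams compute_psth
#' @param response_window,baseline_window windows in seconds.
#' @return numeric vector (Hz), one element per event.
#' @export
per_event_amplitudes <- function(spikes, event_times,
                                 response_window = c(0.01, 0.05),
                                 baseline_window = c(-0.2, 0)) {
  spikes <- sort(spikes)
  resp <- window_counts(spikes, event_times,
                        response_window[1], response_window[2]) /
    diff(response_window)
  base <- window_counts(spikes, event_times,
                        baseline_window[1], baseline_window[2]) /
    diff(baseline_window)
  resp - base
}

#' Response profile of one unit for both sound classes
#'
#' Computes, from trial-aligned activity, the baseline statistics and
#' evoked amplitudes that feed the responsiveness criterion and the
#' modulation index. The baseline SD is the standard deviation of the
#' trial-averaged firing rate across 5 ms bins in the 200 ms preceding
#' stimulus onset; z-scores are amplitude divided by that SD.
#'
#' @param spikes sorted spike times (s) of one unit.
#' @param self_times,random_times retained sound onsets from
#'   [select_sounds()].
#' @param bin_width PSTH bin width (s) used for the baseline SD.
#' @return list of class `ss_profile`: `baseline_mean`, `baseline_sd`,
#'   `amp_random`, `amp_self`, `z_random`, `z_self`, `is_responsive`,
#'   `per_trial_amp_random`, `per_trial_amp_self`, `n_trials_random`,
#'   `n_trials_self`.
#' @export
response_profile <- function(spikes, self_times, random_times,
                             bin_width = 0.005) {
  spikes <- sort(spikes)
  all_ev <- sort(c(self_times, random_times))
  if (length(all_ev) == 0) stop("no events to profile", call. = FALSE)

  psth_all <- compute_psth(spikes, all_ev, window = c(-0.2, 0.05),
                           bin_width = bin_width)
  mids <- psth_all$bin_edges[-length(psth_all$bin_edges)] + bin_width / 2
  base_bins <- psth_all$rate[mids < 0]
  baseline_mean <- mean(base_bins)
  baseline_sd <- stats::sd(base_bins)

  amp_one <- function(ev) {
    if (length(ev) == 0) {
      return(list(amp = NA_real_, per_trial = numeric(0), frac_hit = NA_real_))
    }
    per_trial <- per_event_amplitudes(spikes, ev)
    hits <- window_counts(spikes, ev, 0.01, 0.05) > 0
    list(amp = mean(per_trial), per_trial = per_trial,
         frac_hit = mean(hits))
  }
  s <- amp_one(self_times)
  r <- amp_one(random_times)

  z <- function(amp) if (is.na(amp) || baseline_sd == 0) NA_real_ else
    amp / baseline_sd
  z_self <- z(s$amp)
  z_random <- z(r$amp)

  if (baseline_sd > 0) {
    responsive <- isTRUE(max(z_random, z_self, na.rm = TRUE) >= 2)
  } else {
    # silent-baseline convention: responsive iff a positive amplitude is
    # backed by spikes in the response window on at least 25% of trials
    responsive <- isTRUE((!is.na(r$amp) && r$amp > 0 && r$frac_hit >= 0.25) ||
                         (!is.na(s$amp) && s$amp > 0 && s$frac_hit >= 0.25))
  }

  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 amp_random = r$amp, amp_self = s$amp,
                 z_random = z_random, z_self = z_self,
                 is_responsive = responsive,
                 per_trial_amp_random = r$per_trial,
                 per_trial_amp_self = s$per_trial,
                 n_trials_random = length(random_times),
                 n_trials_self = length(self_times)),
            class = "ss_profile")
}

#' Auditory responsiveness criterion
#'
#' A unit is auditory responsive when its evoked amplitude for either
#' sound class is at least twice the SD of its 5 ms-binned baseline rate
#' (inclusive threshold). Units with a silent baseline follow the
#' convention documented in [response_profile()].
#'
#' @param profile an `ss_profile`.
#' @return logical.
#' @export
classify_responsive <- function(profile) {
  stopifnot(inherits(profile, "ss_profile"))
  profile$is_responsive
}

#' Preparatory (pre-press) activity of one unit
#'
#' Firing rate in 100 ms bins over the second preceding selected lever
#' presses, expressed relative to the rate in the reference bin 1000--900
#' ms before the press. The summary statistic is the mean rate change over
#' the final 200 ms before the press.
#'
#' @param spikes sorted spike times (s).
#' @param press_times presses from [select_preparatory_presses()].
#' @param bin_width bin width (s).
#' @return list: `bin_edges` (s relative to press), `delta_hz` (per bin),
#'   `summary_delta_hz`, `n_press`, `reference_hz`.
#' @export
preparatory_activity <- function(spikes, press_times, bin_width = 0.1) {
  if (length(press_times) == 0) stop("no presses selected", call. = FALSE)
  psth <- compute_psth(spikes, press_times, window = c(-1, 0),
                       bin_width = bin_width)
  ref <- psth$rate[1]                       # [-1000, -900) ms
  delta <- psth$rate - ref
  mids <- psth$bin_edges[-length(psth$bin_edges)] + bin_width / 2
  summary_delta <- mean(psth$rate[mids > -0.2]) - ref
  list(bin_edges = psth$bin_edges, delta_hz = delta,
       summary_delta_hz = summary_delta, n_press = psth$n_trials,
       reference_hz = ref)
}

#' Paired-pulse adaptation ratio
#'
#' For sound pairs at a set of inter-pulse intervals, the ratio of the
#' trial-averaged response to the second sound over that to the first
#' (each a 10--50 ms rate minus the 0--200 ms baseline preceding the
#' first sound). Pairs at 100 ms are reported but excluded from the
#' summary because first-sound responses can outlast 100 ms.
#'
#' @param spikes sorted spike times (s).
#' @param pairs data.frame with columns `first_time` (s) and `ipi_s`.
#' @param exclude_ipi intervals (s) dropped from the summary.
#' @return list: `by_interval` data.frame (`ipi_s`, `resp1_hz`,
#'   `resp2_hz`, `ratio`, `n_pairs`, `valid`) and `summary` (same frame
#'   restricted to valid, non-excluded intervals).
#' @export
paired_pulse_ratio <- function(spikes, pairs, exclude_ipi = 0.1) {
  stopifnot(is.data.frame(pairs),
            all(c("first_time", "ipi_s") %in% names(pairs)))
  spikes <- sort(spikes)
  out <- lapply(split(pairs, pairs$ipi_s), function(p) {
    base <- window_counts(spikes, p$first_time, -0.2, 0) / 0.2
    r1 <- window_counts(spikes, p$first_time, 0.01, 0.05) / 0.04 - base
    r2 <- window_counts(spikes, p$first_time + p$ipi_s, 0.01, 0.05) / 0.04 -
      base
    m1 <- mean(r1); m2 <- mean(r2)
    data.frame(ipi_s = p$ipi_s[1], resp1_hz = m1, resp2_hz = m2,
               ratio = if (m1 > 0) m2 / m1 else NA_real_,
               n_pairs = nrow(p), valid = m1 > 0)
  })
  by_interval <- do.call(rbind, out)
  rownames(by_interval) <- NULL
  keep <- by_interval$valid & !(by_interval$ipi_s %in% exclude_ipi)
  list(by_interval = by_interval, summary = by_interval[keep, , drop = FALSE])
}
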