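#' Light-evoked firing-rate change per 5 ms bin
#'
#' Trial-averaged PSTH from 100 ms before to 100 ms after light onset in
#' 5 ms bins; for each post-onset bin the difference in firing rate
#' (delta FR) relative to the mean baseline rate (0--100 ms before
#' onset).
#'
#' @param spikes sorted spike times (s).
#' @param light_onsets light-pulse onset times (s).
#' @param bin_width bin width (s).
#' @param window half-width of the PSTH around onset (s).
#' @return list: `delta_hz` (one value per post-onset bin), `bin_edges`
#'   (s, post-onset), `counts_per_bin` (total spikes per post-onset bin
#'   across trials), `baseline_hz`, `n_baseline_spikes`, `n_trials`.
#' @export
opto_delta_fr <- function(spikes, light_onsets, bin_width = 0.005,
                          window = 0.1) {
  psth <- compute_psth(spikes, light_onsets,
                       window = c(-window, window), bin_width = bin_width)
  n_bins <- length(psth$rate)
  post <- seq(n_bins / 2 + 1, n_bins)
  baseline_hz <- mean(psth$rate[seq_len(n_bins / 2)])
  list(delta_hz = psth$rate[post] - baseline_hz,
       bin_edges = psth$bin_edges[c(post, n_bins + 1)],
       counts_per_bin = colSums(psth$counts[, post, drop = FALSE]),
       baseline_hz = baseline_hz,
       n_baseline_spikes = sum(psth$counts[, seq_len(n_bins / 2)]),
       n_trials = psth$n_trials)
}

#' Surrogate-PSTH null distribution for light responses
#'
#' Builds the chance distribution of per-bin delta FR values by cutting
#' 200 ms segments at random from the baseline periods of the session
#' (times at least 200 ms away from any post-light epoch). Each surrogate
#' draws as many segments as there are light presentations, treats the
#' first 100 ms of each segment as baseline and the second 100 ms as
#' response, and yields one delta FR per 5 ms response bin; the values of
#' all surrogates and bins are pooled into a single null distribution.
#' The per-bin p value of the observed PSTH is the fraction of pooled
#' null values at least as large (positive observed delta) or at least as
#' small (negative) as the observed value. Segment starts are drawn on
#' the 5 ms bin grid so surrogate binning matches the PSTH binning.
#'
#' @inheritParams opto_delta_fr
#' @param n_surrogates number of surrogate PSTHs.
#' @param seed optional RNG seed for reproducible draws.
#' @return list: `null_delta_hz` (pooled, length `n_surrogates * 20`),
#'   `p_per_bin`, plus the observed components of [opto_delta_fr()].
#' @export
opto_surrogate_null <- function(spikes, light_onsets, n_surrogates = 1000,
                                bin_width = 0.005, window = 0.1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- opto_delta_fr(spikes, light_onsets, bin_width, window)
  n_trials <- obs$n_trials
  n_resp_bins <- as.integer(round(window / bin_width))
  seg_len <- 2L * n_resp_bins                 # 200 ms of 5 ms bins

  T_end <- max(c(spikes, light_onsets + 2 * window))
  n_grid <- floor(T_end / bin_width)
  grid_counts <- tabulate(pmin(floor(sort(spikes) / bin_width) + 1L, n_grid),
                          nbins = n_grid)

  # allowed segment starts: [s, s + 0.2] at least 0.2 s from every
  # post-light epoch [onset, onset + window]
  starts_t <- (seq_len(n_grid - seg_len) - 1L) * bin_width
  ok <- rep(TRUE, length(starts_t))
  for (on in light_onsets) {
    ok <- ok & (starts_t + seg_len * bin_width <= on - 2 * window |
                starts_t >= on + 3 * window)
  }
  allowed <- which(ok)
  if (length(allowed) < 10) {
    stop(sprintf(
      "insufficient baseline: need >= 10 candidate 200 ms segments, found %d",
      length(allowed)), call. = FALSE)
  }

  n_seg <- n_surrogates * n_trials
  s <- sample(allowed, n_seg, replace = TRUE)
  sid <- rep(seq_len(n_surrogates), each = n_trials)
  cs <- c(0, cumsum(grid_counts))
  base_counts <- cs[s + n_resp_bins] - cs[s]
  base_sum <- rowsum(base_counts, sid)
  resp_idx <- outer(s + n_resp_bins - 1L, seq_len(n_resp_bins), "+")
  resp_mat <- matrix(grid_counts[resp_idx], nrow = n_seg)
  resp_sum <- rowsum(resp_mat, sid)
  null_delta <- resp_sum / (bin_width * n_trials) -
    as.vector(base_sum) / (window * n_trials)
  null_pool <- as.vector(null_delta)

  p <- vapply(obs$delta_hz, function(d) {
    if (d > 0) mean(null_pool >= d)
    else if (d < 0) mean(null_pool <= d)
    else 1
  }, numeric(1))

  c(obs, list(null_delta_hz = null_pool, p_per_bin = p,
              n_surrogates = n_surrogates))
}

#' Classify a unit's light response
#'
#' Latency is the end time of the first 5 ms bin with positive delta FR
#' and p < `alpha_latency`; with this convention a latency of at most
#' 10 ms admits exactly the first two bins. A unit is
#' `excitatory_short_latency` when that latency is at most 10 ms
#' (terminal stimulation) or 15 ms (soma stimulation) and it fired at
#' least `min_spikes_excitatory` spikes in the latency bin across trials.
#' It is `inhibitory` when at least three consecutive bins in the first
#' 50 ms have negative delta FR with p < `alpha_inhibitory` and it fired
#' at least `min_baseline_spikes` baseline spikes. The excitatory label
#' takes precedence.
#'
#' @param response result of [opto_surrogate_null()].
#' @param mode `"terminal"` (10 ms cutoff) or `"soma"` (15 ms).
#' @param alpha_latency p threshold defining the latency bin.
#' @param alpha_inhibitory p threshold for suppressed bins.
#' @param min_spikes_excitatory,min_baseline_spikes spike-count guards
#'   against false positives in sparsely firing units.
#' @return list: `label`, `latency_ms` (NA unless excitatory), `p_min`.
#' @export
classify_opto <- function(response, mode = c("terminal", "soma"),
                          alpha_latency = 0.001, alpha_inhibitory = 0.05,
                          min_spikes_excitatory = 10,
                          min_baseline_spikes = 20) {
  mode <- match.arg(mode)
  cutoff_ms <- if (mode == "terminal") 10 else 15
  bw_ms <- 1000 * diff(response$bin_edges[1:2])
  d <- response$delta_hz
  p <- response$p_per_bin

  label <- "none"
  latency_ms <- NA_real_
  sig <- which(d > 0 & p < alpha_latency)
  if (length(sig) > 0) {
    first <- sig[1]
    lat <- first * bw_ms                       # end time of the bin
    if (lat <= cutoff_ms &&
        response$counts_per_bin[first] >= min_spikes_excitatory) {
      label <- "excitatory_short_latency"
      latency_ms <- lat
    }
  }
  if (label == "none") {
    in50 <- seq_len(min(length(d), as.integer(50 / bw_ms)))
    supp <- d[in50] < 0 & p[in50] < alpha_inhibitory
    r <- rle(supp)
    if (any(r$values & r$lengths >= 3) &&
        response$n_baseline_spikes >= min_baseline_spikes) {
      label <- "inhibitory"
    }
  }
  list(label = label, latency_ms = latency_ms, p_min = min(p))
}

#' Classify every unit of an opto session
#'
#' @param session a session list (`units`, `spikes`, `events`) whose
#'   events contain `light_on` rows.
#' @param mode,n_surrogates,seed see [classify_opto()] and
#'   [opto_surrogate_null()].
#' @return data.frame: `unit_id`, `depth_um`, `label`, `latency_ms`,
#'   `p_min`.
#' @export
opto_map_session <- function(session, mode = "terminal",
                             n_surrogates = 1000, seed = 1) {
  onsets <- session$events$time_s[session$events$event_type == "light_on"]
  if (length(onsets) == 0) stop("session has no light_on events")
  set.seed(seed)
  res <- lapply(seq_len(nrow(session$units)), function(i) {
    uid <- session$units$unit_id[i]
    sp <- session$spikes$time_s[session$spikes$unit_id == uid]
    resp <- opto_surrogate_null(sp, onsets, n_surrogates = n_surrogates)
    cl <- classify_opto(resp, mode = mode)
    data.frame(unit_id = uid, depth_um = session$units$depth_um[i],
               label = cl$label, latency_ms = cl$latency_ms,
               p_min = cl$p_min)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fractions of light-responsive units by cortical layer
#'
#' Splits units at 600 um below the surface (upper vs lower layers) and
#' reports, per layer, the fraction of units carrying each label relative
#' to the total number of units recorded in that layer.
#'
#' @param opto_table data.frame from [opto_map_session()].
#' @param split_um depth separating upper from lower layers.
#' @return data.frame: `layer`, `n_units`, `n_excitatory`,
#'   `n_inhibitory`, `pct_excitatory`, `pct_inhibitory`.
#' @export
population_fractions <- function(opto_table, split_um = 600) {
  layer <- ifelse(opto_table$depth_um < split_um, "upper", "lower")
  res <- lapply(c("upper", "lower"), function(l) {
    x <- opto_table[layer == l, , drop = FALSE]
    n <- nrow(x)
    ne <- sum(x$label == "excitatory_short_latency")
    ni <- sum(x$label == "inhibitory")
    data.frame(layer = l, n_units = n, n_excitatory = ne,
               n_inhibitory = ni,
               pct_excitatory = if (n) fraction_pct(ne, n) else 0,
               pct_inhibitory = if (n) fraction_pct(ni, n) else 0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
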