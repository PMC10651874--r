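#' Generate a behavioral and stimulus event log
#'
#' Simulates one session of bout-structured lever pressing. Every press
#' triggers a `sound_self` event at the press time; identical sounds are
#' also presented randomly with inter-sound gaps drawn uniformly from
#' `random_sound_interval`. Presses come in bouts (geometric bout length,
#' uniform inter-press intervals) separated by quiescent pauses, which is
#' the structure the event-selection rules assume. Rewards and lever
#' releases are included so downstream code is exercised with event types
#' it must ignore.
#'
#' @param config a [sim_config()].
#' @param .reseed set the RNG from `config$seed` before drawing (default
#'   `TRUE`; internal callers that manage the RNG stream pass `FALSE`).
#' @return a data.frame with columns `time_s`, `event_type` (one of
#'   `press`, `release`, `sound_self`, `sound_random`, `reward`,
#'   `light_on`) and `duration_s`, sorted by time.
#' @export
generate_behavior <- function(config, .reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$session_duration < 0) stop("negative session duration")
  if (.reseed) set.seed(config$seed)
  T_end <- config$session_duration
  if (T_end == 0) {
    return(data.frame(time_s = numeric(0), event_type = character(0),
                      duration_s = numeric(0)))
  }

  ## lever-press bouts
  press_times <- numeric(0)
  t <- stats::runif(1, 5, 15)          # settling period before first bout
  while (t < T_end) {
    n_bout <- stats::rgeom(1, 1 / config$bout_length_mean) + 1L
    gaps <- stats::runif(n_bout, config$press_interval[1],
                         config$press_interval[2])
    bout <- t + cumsum(gaps) - gaps[1]
    bout <- bout[bout < T_end]
    press_times <- c(press_times, bout)
    if (length(bout) == 0) break
    t <- bout[length(bout)] +
      stats::runif(1, config$bout_pause[1], config$bout_pause[2])
  }

  ## random sounds over the whole session
  n_max <- ceiling(T_end / config$random_sound_interval[1]) + 1L
  gaps <- stats::runif(n_max, config$random_sound_interval[1],
                       config$random_sound_interval[2])
  rnd_times <- cumsum(gaps)
  rnd_times <- rnd_times[rnd_times < T_end]

  hold <- stats::runif(length(press_times), 0.25, 0.75)
  ev <- rbind(
    data.frame(time_s = press_times, event_type = "press",
               duration_s = hold),
    data.frame(time_s = press_times, event_type = "sound_self",
               duration_s = config$sound_duration),
    data.frame(time_s = pmin(press_times + hold, T_end),
               event_type = "release", duration_s = 0),
    data.frame(time_s = pmin(press_times + 0.15, T_end),
               event_type = "reward", duration_s = 0),
    data.frame(time_s = rnd_times, event_type = "sound_random",
               duration_s = config$sound_duration)
  )
  ev <- ev[order(ev$time_s, ev$event_type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## Draw spike times for one linear ramp ending at `t_end`, rising from 0 at
## t_end - onset to `amp` Hz at t_end. Inverse-CDF sampling: F(s) = s^2 on
## the normalized ramp support.
ramp_spikes <- function(t_end, onset, amp) {
  n <- stats::rpois(1, 0.5 * amp * onset)
  if (n == 0) return(numeric(0))
  t_end - onset + onset * sqrt(stats::runif(n))
}

#' Generate spike trains and waveforms for one session
#'
#' Realizes each unit as an inhomogeneous Poisson process: a homogeneous
#' baseline (rate drawn from the configured log-normal), an evoked
#' transient confined to 10--50 ms after every sound (amplitude
#' `evoked_amp_random` times the adaptation gain, and additionally times
#' the attenuation factor for self-generated sounds), and a linear
#' firing-rate ramp rising over the `ramp_onset` seconds preceding each
#' press. All components are non-negative, so the superposition property
#' of Poisson processes lets each be sampled independently.
#'
#' @param config a [sim_config()].
#' @param log event log from [generate_behavior()].
#' @param animal_id,genotype identity attached to every unit.
#' @param .reseed see [generate_behavior()].
#' @return list with data.frames `units` (unit_id, animal_id, genotype,
#'   depth_um plus ground-truth columns `true_class`, `true_baseline_hz`),
#'   `spikes` (unit_id, time_s) and `waveforms` (unit_id, sample_index,
#'   amplitude).
#' @export
generate_spikes <- function(config, log, animal_id = "animal01",
                            genotype = "WT", .reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(log))
  if (.reseed) set.seed(config$seed)
  T_end <- config$session_duration
  n_units <- config$n_units_per_animal

  sounds <- log[log$event_type %in% c("sound_self", "sound_random"), ,
                drop = FALSE]
  sounds <- sounds[order(sounds$time_s), , drop = FALSE]
  dt_prev <- c(Inf, diff(sounds$time_s))
  gain <- adaptation_gain(dt_prev, config$adaptation_depth,
                          config$adaptation_tau)
  is_self <- sounds$event_type == "sound_self"
  self_ordinal <- cumsum(is_self)
  press_times <- log$time_s[log$event_type == "press"]

  depth <- stats::runif(n_units, config$depth_range[1], config$depth_range[2])
  base_rate <- stats::rlnorm(n_units, config$baseline_rate_meanlog,
                             config$baseline_rate_sdlog)
  cls <- ifelse(stats::runif(n_units) < config$interneuron_fraction,
                "pIN", "pPN")

  units <- data.frame(
    unit_id = sprintf("%s_u%02d", animal_id, seq_len(n_units)),
    animal_id = animal_id,
    genotype = genotype,
    depth_um = depth,
    true_class = cls,
    true_baseline_hz = base_rate
  )

  spike_list <- vector("list", n_units)
  wf_list <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    b <- base_rate[i]
    n_base <- stats::rpois(1, b * T_end)
    sp <- stats::runif(n_base, 0, T_end)

    if (nrow(sounds) > 0 && config$evoked_amp_random > 0) {
      amp <- config$evoked_amp_random * gain
      if (any(is_self)) {
        a_i <- attenuation_for(config, depth[i], genotype,
                               self_ordinal[is_self])
        amp[is_self] <- amp[is_self] * a_i
      }
      n_ev <- stats::rpois(nrow(sounds), amp * 0.04)
      if (sum(n_ev) > 0) {
        t0 <- rep(sounds$time_s, n_ev)
        sp <- c(sp, t0 + 0.01 + stats::runif(sum(n_ev)) * 0.04)
      }
    }

    if (config$ramp_amplitude > 0 && length(press_times) > 0) {
      for (p in press_times) {
        sp <- c(sp, ramp_spikes(p, config$ramp_onset, config$ramp_amplitude))
      }
    }
    sp <- sp[sp >= 0 & sp <= T_end]
    spike_list[[i]] <- data.frame(unit_id = units$unit_id[i],
                                  time_s = sort(sp))
    w <- synth_waveform(config$waveform_templates, cls[i])
    wf_list[[i]] <- data.frame(unit_id = units$unit_id[i],
                               sample_index = seq_along(w), amplitude = w)
  }
  list(units = units,
       spikes = do.call(rbind, spike_list),
       waveforms = do.call(rbind, wf_list))
}

## Biphasic trough-then-peak waveform on the standard extraction window
## (495 us before to 1287 us after the trough at `sample_us` spacing).
## The trough is a negative Gaussian whose FWHM equals the class half-width;
## the after-potential is a smaller positive Gaussian centred trough-to-peak
## microseconds later.
synth_waveform <- function(tpl, class) {
  p <- tpl[[class]]
  sd_frac <- tpl$sd_frac
  su <- tpl$sample_us
  t2p <- stats::rnorm(1, p$trough_to_peak, sd_frac * p$trough_to_peak)
  hw <- stats::rnorm(1, p$half_width, sd_frac * p$half_width)
  t2p <- max(t2p, 2.5 * su)
  hw <- max(hw, 1.5 * su)
  n_pre <- floor(495 / su)
  n_post <- floor(1287 / su)
  t <- (-n_pre:n_post) * su
  sig_tr <- hw / (2 * sqrt(2 * log(2)))
  peak_amp <- 0.35
  sig_pk <- 0.45 * t2p
  w <- -exp(-0.5 * (t / sig_tr)^2) + peak_amp * exp(-0.5 * ((t - t2p) / sig_pk)^2)
  w + stats::rnorm(length(w), 0, 0.01)
}

#' Simulate one complete session (events + units + spikes + waveforms)
#'
#' @inheritParams generate_spikes
#' @return a `session` list with elements `units`, `spikes`, `events`,
#'   `waveforms`.
#' @export
simulate_session <- function(config, animal_id = "animal01",
                             genotype = "WT", .reseed = TRUE) {
  if (.reseed) set.seed(config$seed)
  ev <- generate_behavior(config, .reseed = FALSE)
  sp <- generate_spikes(config, ev, animal_id, genotype, .reseed = FALSE)
  structure(list(units = sp$units, spikes = sp$spikes, events = ev,
                 waveforms = sp$waveforms), class = "ss_session")
}

#' Simulate a full cohort: one session per animal per genotype
#'
#' Animals are simulated sequentially from a single RNG stream seeded with
#' `config$seed`, so a cohort is reproducible as a whole.
#'
#' @param config a [sim_config()].
#' @return list of `session` objects, named by animal id.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  sessions <- list()
  for (g in config$genotypes) {
    for (i in seq_len(config$n_animals_per_genotype)) {
      id <- sprintf("%s_m%02d", tolower(g), i)
      sessions[[id]] <- simulate_session(config, animal_id = id,
                                         genotype = g, .reseed = FALSE)
    }
  }
  sessions
}

#' Simulate an optogenetic stimulation session
#'
#' Light pulses are delivered every 2--3 s (configurable). With an opsin
#' present, a configured fraction of units deeper than
#' `opto$excited_min_depth` receive short-latency excitation (a fixed
#' per-unit latency drawn from `latency_range` with sub-millisecond
#' per-spike jitter), and a fraction of all units are transiently
#' suppressed after light onset. With `opsin = FALSE` no unit's rate
#' depends on the light.
#'
#' @param config a [sim_config()]; the `opto` element controls the session.
#' @param opsin logical; whether light can drive responses.
#' @param n_units number of units (defaults to `n_units_per_animal`).
#' @param animal_id,genotype identity labels.
#' @param .reseed see [generate_behavior()].
#' @return a `session` list; `units` carries ground-truth columns
#'   `true_opto` (one of `excited`, `inhibited`, `none`) and
#'   `true_latency_s`.
#' @export
generate_opto_session <- function(config, opsin = TRUE, n_units = NULL,
                                  animal_id = "opto01", genotype = "WT",
                                  .reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (.reseed) set.seed(config$seed)
  op <- config$opto
  if (is.null(n_units)) n_units <- config$n_units_per_animal
  T_end <- op$duration

  gaps <- stats::runif(ceiling(T_end / op$pulse_period[1]) + 1L,
                       op$pulse_period[1], op$pulse_period[2])
  onsets <- 5 + cumsum(gaps) - gaps[1]
  onsets <- onsets[onsets < T_end - op$pulse_duration]
  events <- data.frame(time_s = onsets, event_type = "light_on",
                       duration_s = op$pulse_duration)

  depth <- stats::runif(n_units, config$depth_range[1], config$depth_range[2])
  base_rate <- stats::rlnorm(n_units, config$baseline_rate_meanlog,
                             config$baseline_rate_sdlog)
  cls <- ifelse(stats::runif(n_units) < config$interneuron_fraction,
                "pIN", "pPN")
  deep <- depth > op$excited_min_depth
  excited <- opsin & deep & stats::runif(n_units) < op$fraction_excited
  inhibited <- opsin & !excited & stats::runif(n_units) < op$fraction_inhibited
  latency <- ifelse(excited,
                    stats::runif(n_units, op$latency_range[1],
                                 op$latency_range[2]), NA_real_)

  units <- data.frame(
    unit_id = sprintf("%s_u%03d", animal_id, seq_len(n_units)),
    animal_id = animal_id, genotype = genotype, depth_um = depth,
    true_class = cls, true_baseline_hz = base_rate,
    true_opto = ifelse(excited, "excited",
                       ifelse(inhibited, "inhibited", "none")),
    true_latency_s = latency
  )

  spike_list <- vector("list", n_units)
  wf_list <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    sp <- stats::runif(stats::rpois(1, base_rate[i] * T_end), 0, T_end)
    if (inhibited[i]) {
      # thin baseline spikes within the suppression window after each pulse
      rel <- outer(sp, onsets, "-")
      in_win <- rowSums(rel >= op$inhibition_onset &
                        rel < op$inhibition_onset + op$inhibition_duration) > 0
      drop <- in_win & stats::runif(length(sp)) > op$inhibition_gain
      sp <- sp[!drop]
    }
    if (excited[i]) {
      n_ev <- stats::rpois(length(onsets), op$spikes_per_pulse)
      t0 <- rep(onsets, n_ev) + latency[i] +
        stats::rnorm(sum(n_ev), 0, op$jitter_sd)
      sp <- c(sp, t0)
    }
    sp <- sp[sp >= 0 & sp <= T_end]
    spike_list[[i]] <- data.frame(unit_id = units$unit_id[i],
                                  time_s = sort(sp))
    w <- synth_waveform(config$waveform_templates, cls[i])
    wf_list[[i]] <- data.frame(unit_id = units$unit_id[i],
                               sample_index = seq_along(w), amplitude = w)
  }
  structure(list(units = units, spikes = do.call(rbind, spike_list),
                 events = events, waveforms = do.call(rbind, wf_list)),
            class = "ss_session")
}
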