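#' Configuration for synthetic recording sessions
#'
#' Builds a validated list of generator parameters describing one cohort of
#' head-fixed lever-pressing sessions: bout-structured pressing with
#' press-triggered sounds, randomly timed presentations of the same sound,
#' Poisson background spiking with a brief evoked transient, pre-press
#' ramping, inter-sound adaptation, two waveform classes, and optogenetic
#' light-pulse sessions.
#'
#' The evoked transient is confined to 10--50 ms after sound onset. Its
#' amplitude for a random sound is `evoked_amp_random` (Hz above baseline);
#' for a self-generated sound it is multiplied by the attenuation factor
#' `a`, so the analytic modulation index of a unit is `(a - 1) / (a + 1)`.
#' Successive sounds adapt with gain `g(dt) = 1 - A * exp(-dt / tau)` where
#' `dt` is the time since the previous sound of any type.
#'
#' @param seed integer seed; the same seed and configuration reproduce
#'   byte-identical sessions.
#' @param session_duration session length in seconds.
#' @param n_animals_per_genotype,n_units_per_animal cohort shape.
#' @param genotypes character vector of genotype labels.
#' @param baseline_rate_meanlog,baseline_rate_sdlog log-normal parameters of
#'   per-unit baseline firing rates (Hz).
#' @param evoked_amp_random evoked amplitude (Hz above baseline, within the
#'   10--50 ms window) for randomly timed sounds.
#' @param attenuation_factor attenuation `a` applied to self-generated
#'   sounds: a single non-negative number, a named vector with one entry per
#'   genotype, or a function `f(depth_um, genotype, sound_ordinal)` returning
#'   `a` per self-generated sound (used to simulate depth- or
#'   experience-dependent attenuation).
#' @param ramp_amplitude firing-rate increase (Hz) reached at the moment of
#'   the lever press; the ramp rises linearly from zero starting
#'   `ramp_onset` seconds before the press.
#' @param ramp_onset seconds before the press at which the ramp starts.
#' @param adaptation_depth,adaptation_tau parameters `A` (dimensionless,
#'   in `[0, 1]`) and `tau` (seconds) of the adaptation gain.
#' @param press_interval uniform range (s) of intervals between presses
#'   within a bout.
#' @param bout_length_mean mean number of presses per bout (geometric).
#' @param bout_pause uniform range (s) of pauses between bouts.
#' @param random_sound_interval uniform range (s) between random sounds.
#' @param sound_duration stimulus duration in seconds.
#' @param interneuron_fraction probability that a unit belongs to the
#'   narrow-spiking class.
#' @param depth_range uniform range (micrometres) of unit depths below the
#'   cortical surface.
#' @param waveform_templates list with elements `pPN` and `pIN`, each a list
#'   with `trough_to_peak` and `half_width` means in microseconds, plus
#'   `sd_frac`, the relative SD of both features, and `sample_us`, the
#'   waveform sampling interval in microseconds.
#' @param opto list of optogenetic-session parameters: `duration` (s),
#'   `pulse_period` (uniform range, s), `pulse_duration` (s),
#'   `fraction_excited` (of units deeper than `excited_min_depth`),
#'   `excited_min_depth` (um), `latency_range` (s), `jitter_sd` (s),
#'   `spikes_per_pulse` (mean evoked spikes per pulse for excited units),
#'   `fraction_inhibited`, `inhibition_onset` (s), `inhibition_duration`
#'   (s), and `inhibition_gain` (multiplier on baseline rate while
#'   suppressed).
#'
#' @return an object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, session_duration = 600)
#' log <- generate_behavior(cfg)
#' head(log)
sim_config <- function(seed = 1,
                       session_duration = 7200,
                       n_animals_per_genotype = 9,
                       n_units_per_animal = 20,
                       genotypes = c("WT", "DF16A"),
                       baseline_rate_meanlog = log(4),
                       baseline_rate_sdlog = 0.6,
                       evoked_amp_random = 20,
                       attenuation_factor = c(WT = 0.6, DF16A = 0.852),
                       ramp_amplitude = 3,
                       ramp_onset = 0.6,
                       adaptation_depth = 0.5,
                       adaptation_tau = 0.3,
                       press_interval = c(2, 6),
                       bout_length_mean = 15,
                       bout_pause = c(30, 120),
                       random_sound_interval = c(5, 10),
                       sound_duration = 0.1,
                       interneuron_fraction = 0.14,
                       depth_range = c(100, 1100),
                       waveform_templates = list(
                         pPN = list(trough_to_peak = 700, half_width = 300),
                         pIN = list(trough_to_peak = 300, half_width = 150),
                         sd_frac = 0.10,
                         sample_us = 33
                       ),
                       opto = list(
                         duration = 600,
                         pulse_period = c(2, 3),
                         pulse_duration = 0.1,
                         fraction_excited = 0.08,
                         excited_min_depth = 600,
                         latency_range = c(0.002, 0.008),
                         jitter_sd = 0.0004,
                         spikes_per_pulse = 1.5,
                         fraction_inhibited = 0.04,
                         inhibition_onset = 0.01,
                         inhibition_duration = 0.04,
                         inhibition_gain = 0.15
                       )) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    is.numeric(session_duration), length(session_duration) == 1,
    n_animals_per_genotype >= 1, n_units_per_animal >= 1,
    evoked_amp_random >= 0,
    ramp_amplitude >= 0, ramp_onset > 0,
    adaptation_depth >= 0, adaptation_depth <= 1, adaptation_tau > 0,
    length(press_interval) == 2, diff(press_interval) >= 0,
    press_interval[1] > 0,
    length(random_sound_interval) == 2, random_sound_interval[1] > 0,
    diff(random_sound_interval) >= 0,
    interneuron_fraction >= 0, interneuron_fraction <= 1,
    length(depth_range) == 2, depth_range[1] < depth_range[2]
  )
  if (session_duration < 0) {
    stop("`session_duration` must be non-negative", call. = FALSE)
  }
  if (is.function(attenuation_factor)) {
    # accepted as-is; evaluated per self-generated sound
  } else if (is.numeric(attenuation_factor)) {
    if (any(attenuation_factor < 0)) {
      stop("`attenuation_factor` must be >= 0", call. = FALSE)
    }
    if (length(attenuation_factor) > 1 &&
        !all(genotypes %in% names(attenuation_factor))) {
      stop("named `attenuation_factor` must cover every genotype",
           call. = FALSE)
    }
  } else {
    stop("`attenuation_factor` must be numeric or a function", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    session_duration = session_duration,
    n_animals_per_genotype = as.integer(n_animals_per_genotype),
    n_units_per_animal = as.integer(n_units_per_animal),
    genotypes = genotypes,
    baseline_rate_meanlog = baseline_rate_meanlog,
    baseline_rate_sdlog = baseline_rate_sdlog,
    evoked_amp_random = evoked_amp_random,
    attenuation_factor = attenuation_factor,
    ramp_amplitude = ramp_amplitude,
    ramp_onset = ramp_onset,
    adaptation_depth = adaptation_depth,
    adaptation_tau = adaptation_tau,
    press_interval = press_interval,
    bout_length_mean = bout_length_mean,
    bout_pause = bout_pause,
    random_sound_interval = random_sound_interval,
    sound_duration = sound_duration,
    interneuron_fraction = interneuron_fraction,
    depth_range = depth_range,
    waveform_templates = waveform_templates,
    opto = opto
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Resolve the attenuation factor for a set of self-generated sounds
#'
#' @param cfg a `sim_config`.
#' @param depth_um unit depth.
#' @param genotype unit genotype.
#' @param ordinals ordinal positions (1-based) of the self-generated sounds
#'   within the session.
#' @return numeric vector of attenuation factors, one per sound.
#' @keywords internal
attenuation_for <- function(cfg, depth_um, genotype, ordinals) {
  a <- cfg$attenuation_factor
  if (is.function(a)) {
    vapply(ordinals, function(i) a(depth_um, genotype, i), numeric(1))
  } else if (length(a) > 1) {
    rep(unname(a[[genotype]]), length(ordinals))
  } else {
    rep(unname(a), length(ordinals))
  }
}

#' Adaptation gain as a function of time since the previous sound
#'
#' `g(dt) = 1 - A * exp(-dt / tau)`: responses recover exponentially from a
#' maximal fractional suppression `A` with time constant `tau`.
#'
#' @param dt seconds since the previous sound (`Inf` for the first sound).
#' @param A adaptation depth in `[0, 1]`.
#' @param tau recovery time constant in seconds.
#' @return gain in `[1 - A, 1]`.
#' @export
#' @examples
#' adaptation_gain(0.4, A = 0.5, tau = 0.3)
adaptation_gain <- function(dt, A = 0.5, tau = 0.3) {
  stopifnot(A >= 0, A <= 1, tau > 0)
  g <- 1 - A * exp(-dt / tau)
  g[!is.finite(dt)] <- 1
  g
}
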