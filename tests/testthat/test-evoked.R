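test_that("PSTH binning follows the half-open convention", {
  p <- compute_psth(spikes = 0, event_times = 0, window = c(0, 0.1),
                    bin_width = 0.005)
  expect_equal(p$counts[1, 1], 1)
  expect_equal(sum(p$counts), 1)

  ev <- (1:100) * 2
  p2 <- compute_psth(spikes_at_offset(ev, 0.020), ev,
                     window = c(-0.2, 0.05), bin_width = 0.005)
  mids <- p2$bin_edges[-length(p2$bin_edges)] + 0.0025
  expect_equal(p2$rate[mids > 0.020 & mids < 0.025], 200)
  expect_equal(sum(p2$rate > 0), 1)
  expect_error(compute_psth(1, numeric(0)), "no events")
  expect_error(compute_psth(1, 0, window = c(0, 0.012), bin_width = 0.005),
               "integer number of bins")
})

test_that("PSTH conserves spike counts", {
  set.seed(1)
  for (i in 1:10) {
    spikes <- sort(runif(300, 0, 100))
    ev <- sort(runif(20, 1, 99))
    p <- compute_psth(spikes, ev, window = c(-0.2, 0.1))
    brute <- sum(sapply(ev, function(t)
      sum(spikes >= t - 0.2 & spikes < t + 0.1)))
    expect_equal(sum(p$counts), brute)
  }
})

test_that("response amplitude is window rate minus baseline rate", {
  ev <- (1:100) * 2
  # one spike at +20 ms per trial, silent baseline: 1/0.040 = 25 Hz
  p <- compute_psth(spikes_at_offset(ev, 0.02), ev, window = c(-0.2, 0.05))
  expect_equal(response_amplitude(p), 25)
  # a stationary train contributes equally to both windows
  grid <- as.vector(outer(ev, seq(-0.1975, 0.0475, by = 0.005), "+"))
  p_stat <- compute_psth(sort(grid), ev, window = c(-0.2, 0.05))
  expect_equal(response_amplitude(p_stat), 0)
  # amplitude is invariant to a constant rate offset
  p_both <- compute_psth(sort(c(grid, ev + 0.02)), ev,
                         window = c(-0.2, 0.05))
  expect_equal(response_amplitude(p_both), 25)
})

test_that("per-event amplitudes use each trial's own baseline", {
  ev <- c(10, 20, 30)
  spikes <- sort(c(10.02, 20.02, 19.9, 19.95))  # trial 2 has baseline spikes
  a <- per_event_amplitudes(spikes, ev)
  expect_equal(a, c(25, 25 - 2 / 0.2, 0))
  expect_equal(per_event_amplitudes(numeric(0), ev), c(0, 0, 0))
})

test_that("responsiveness criterion is inclusive and guards silent baselines", {
  ev <- (1:200) * 2
  # strong responder, silent baseline: silent-baseline convention applies
  prof <- response_profile(spikes_at_offset(ev, 0.02), ev + 0.5, ev)
  expect_equal(prof$baseline_sd, 0)
  expect_true(classify_responsive(prof))
  # fully silent unit is not responsive
  prof0 <- response_profile(numeric(0), ev + 0.5, ev)
  expect_false(classify_responsive(prof0))
})

test_that("responsiveness classification has power and controls false positives", {
  set.seed(31)
  ev_self <- (1:150) * 4
  ev_rand <- (1:150) * 4 + 2
  n_hit <- 0
  for (i in 1:40) {  # z-truth well above 2: evoked 25 Hz on 5 Hz baseline
    base <- sort(runif(rpois(1, 5 * 620), 0, 620))
    ev_sp <- rep(ev_rand, rpois(length(ev_rand), 25 * 0.04)) # random only
    sp <- sort(c(base, ev_sp + 0.01 + runif(length(ev_sp)) * 0.04))
    if (response_profile(sp, ev_self, ev_rand)$is_responsive) n_hit <- n_hit + 1
  }
  expect_gte(n_hit, 38)  # >= 95% power
  n_fp <- 0
  for (i in 1:60) {      # null units
    sp <- sort(runif(rpois(1, 5 * 620), 0, 620))
    if (response_profile(sp, ev_self, ev_rand)$is_responsive) n_fp <- n_fp + 1
  }
  expect_lte(n_fp, 9)    # ~5% nominal plus binomial slack
})

test_that("preparatory activity recovers an injected ramp", {
  cfg <- sim_config(seed = 13, session_duration = 3600,
                    n_units_per_animal = 4, evoked_amp_random = 0,
                    ramp_amplitude = 3, ramp_onset = 0.6,
                    baseline_rate_meanlog = log(5), baseline_rate_sdlog = 0)
  s <- simulate_session(cfg)
  presses <- select_preparatory_presses(s$events, selection_config())
  deltas <- sapply(s$units$unit_id, function(uid) {
    sp <- s$spikes$time_s[s$spikes$unit_id == uid]
    pa <- preparatory_activity(sp, presses)
    expect_equal(pa$delta_hz[1], 0)  # reference bin is zero by construction
    pa$summary_delta_hz
  })
  # ramp mean over the last 200 ms: 3 * (1 - 0.1 / 0.6) = 2.5 Hz
  expect_lt(abs(mean(deltas) - 2.5), 0.5)

  # stationary unit: delta stays within noise of zero
  sp0 <- sort(runif(5 * 3600, 0, 3600))
  pa0 <- preparatory_activity(sp0, presses)
  expect_lt(abs(pa0$summary_delta_hz), 1)
})

test_that("paired-pulse ratio matches the adaptation law and exclusions", {
  # deterministic identical responses: ratio is exactly one
  first <- (1:50) * 5
  pairs <- data.frame(first_time = first, ipi_s = 0.4)
  sp <- sort(c(first + 0.02, first + 0.42))
  ppr <- paired_pulse_ratio(sp, pairs)
  expect_equal(ppr$summary$ratio, 1)

  # simulated pairs under the generator's adaptation law
  cfg <- sim_config(seed = 17, session_duration = 0, evoked_amp_random = 60,
                    adaptation_depth = 0.5, adaptation_tau = 0.3,
                    ramp_amplitude = 0, n_units_per_animal = 1,
                    baseline_rate_meanlog = log(2), baseline_rate_sdlog = 0)
  ipis <- c(0.1, 0.2, 0.4, 0.7, 1.0)
  first <- (seq_len(2500) - 1) * 8 + 5
  ipi_vec <- rep(ipis, length.out = 2500)
  ev <- data.frame(
    time_s = sort(c(first, first + ipi_vec)),
    event_type = "sound_random", duration_s = 0.02)
  cfg$session_duration <- max(ev$time_s) + 5
  set.seed(17)
  gen <- generate_spikes(cfg, ev, .reseed = FALSE)
  ppr2 <- paired_pulse_ratio(gen$spikes$time_s,
                             data.frame(first_time = first, ipi_s = ipi_vec))
  expect_false(0.1 %in% ppr2$summary$ipi_s)  # 100 ms pairs excluded
  expect_true(0.1 %in% ppr2$by_interval$ipi_s)
  got <- ppr2$summary$ratio[ppr2$summary$ipi_s == 0.4]
  expect_lt(abs(got - (1 - 0.5 * exp(-0.4 / 0.3))), 0.08)
  # recovery is monotone in the inter-pulse interval
  expect_true(all(diff(ppr2$summary$ratio) > -0.1))
})
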