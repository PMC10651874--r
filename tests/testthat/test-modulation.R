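test_that("modulation index has the documented fixed points", {
  expect_equal(modulation_index(0.6, 1.0), -0.25)
  expect_equal(modulation_index(3, 3), 0)
  expect_equal(modulation_index(0, 1), -1)
  expect_true(is.na(modulation_index(0, 0)))
})

test_that("MI is antisymmetric, bounded, and inverted by percent reduction", {
  set.seed(41)
  s <- runif(200, 0, 50)
  r <- runif(200, 0, 50)
  mi <- modulation_index(s, r)
  expect_equal(mi, -modulation_index(r, s))
  expect_true(all(abs(mi) <= 1))
  # percent reduction inverts the index exactly
  pr <- percent_reduction(mi)
  expect_equal((1 - pr / 100), (1 + mi) / (1 - mi))
  expect_equal(percent_reduction(-0.25), 40)
})

test_that("per-unit significance classes follow the rank-sum contrast", {
  set.seed(42)
  x <- rnorm(100, 10, 2)
  expect_equal(classify_unit_modulation(x, x), "ns")
  expect_equal(classify_unit_modulation(x - 10, x, alpha = 0.05),
               "attenuated")
  expect_equal(classify_unit_modulation(x + 10, x), "enhanced")
  # two trials per class cannot reach p < 0.05 two-sided
  expect_equal(classify_unit_modulation(c(0, 0.1), c(100, 101)), "ns")
})

test_that("depth bins are half-open with a closed deepest edge", {
  dp <- depth_profile(rep(-0.2, 5), rep(450, 5))
  expect_equal(dp$n, c(0, 5, 0, 0, 0))
  dp2 <- depth_profile(c(-0.3, -0.4), c(1100, 900))
  expect_equal(dp2$n[5], 2)  # 1100 falls in the 900-1100 bin
  dp3 <- depth_profile(-0.1, 700)        # 700 opens the [700, 900) bin
  expect_equal(dp3$n, c(0, 0, 0, 1, 0))
})

test_that("depth-dependent attenuation appears in the depth profile", {
  cfg <- sim_config(
    seed = 23, session_duration = 3600, n_units_per_animal = 40,
    ramp_amplitude = 0,
    attenuation_factor = function(depth_um, genotype, i)
      if (depth_um >= 900) 0.38 else 0.9)
  s <- simulate_session(cfg)
  sel <- select_sounds(s$events)
  mi <- sapply(s$units$unit_id, function(uid) {
    sp <- s$spikes$time_s[s$spikes$unit_id == uid]
    p <- response_profile(sp, sel$self_times, sel$random_times)
    modulation_index(p$amp_self, p$amp_random)
  })
  dp <- depth_profile(mi, s$units$depth_um)
  expect_lt(abs(dp$mean_mi[5] - (0.38 - 1) / (0.38 + 1)), 0.06)  # -0.449
  expect_lt(abs(dp$mean_mi[1] - (0.9 - 1) / (0.9 + 1)), 0.06)    # -0.053
})

test_that("block MIs track a mid-session change in attenuation", {
  step_a <- function(depth_um, genotype, i) if (i <= 300) 0.9 else 0.6
  cfg <- sim_config(seed = 29, session_duration = 7200,
                    n_units_per_animal = 15, ramp_amplitude = 0,
                    attenuation_factor = step_a)
  s <- simulate_session(cfg)
  blocks <- split_blocks(s$events, selection_config())
  expect_false(blocks$excluded)
  bm <- sapply(s$units$unit_id, function(uid) {
    sp <- s$spikes$time_s[s$spikes$unit_id == uid]
    b <- block_modulation(sp, blocks)
    c(b$mi_early, b$mi_late)
  })
  d_got <- mean(bm[2, ]) - mean(bm[1, ])
  d_want <- (0.6 - 1) / (0.6 + 1) - (0.9 - 1) / (0.9 + 1)  # -0.197
  expect_lt(abs(d_got - d_want), 0.05)

  # stationary attenuation: early and late agree
  cfg2 <- sim_config(seed = 31, session_duration = 7200,
                     n_units_per_animal = 8, ramp_amplitude = 0,
                     attenuation_factor = 0.6)
  s2 <- simulate_session(cfg2)
  blocks2 <- split_blocks(s2$events, selection_config())
  bm2 <- sapply(s2$units$unit_id, function(uid) {
    sp <- s2$spikes$time_s[s2$spikes$unit_id == uid]
    b <- block_modulation(sp, blocks2)
    c(b$mi_early, b$mi_late)
  })
  expect_lt(abs(mean(bm2[2, ]) - mean(bm2[1, ])), 0.05)

  # excluded session: both absent
  few <- data.frame(time_s = (1:100) * 4, event_type = "sound_self",
                    duration_s = 0.1)
  b0 <- block_modulation(c(1, 2), split_blocks(few, selection_config()))
  expect_true(is.na(b0$mi_early) && is.na(b0$mi_late))
})

test_that("genotype summary is null-calibrated and flags underpowered designs", {
  set.seed(53)
  units <- data.frame(
    mi = rnorm(120, -0.2, 0.1),
    animal_id = rep(sprintf("m%02d", 1:12), each = 10),
    genotype = rep(c("WT", "DF16A"), each = 60))
  g <- genotype_summary(units, n_boot = 300, seed = 7)
  dmi <- g$genotypes$WT$mean_mi - g$genotypes$DF16A$mean_mi
  expect_lt(abs(dmi), 0.08)
  expect_gt(g$p_ranksum, 0.01)
  expect_false(g$underpowered)

  units1 <- units[units$animal_id %in% c("m01", "m07"), ]
  g1 <- genotype_summary(units1, n_boot = 100, seed = 7)
  expect_true(g1$underpowered)
  expect_true(is.na(g1$p_bootstrap))
})

test_that("parameter recovery holds over a grid of attenuation factors", {
  for (a in c(0.25, 0.75, 1.25)) {
    cfg <- sim_config(seed = 61 + round(100 * a), session_duration = 3600,
                      n_units_per_animal = 25, ramp_amplitude = 0,
                      attenuation_factor = a)
    s <- simulate_session(cfg)
    sel <- select_sounds(s$events)
    mi <- sapply(s$units$unit_id, function(uid) {
      sp <- s$spikes$time_s[s$spikes$unit_id == uid]
      p <- response_profile(sp, sel$self_times, sel$random_times)
      modulation_index(p$amp_self, p$amp_random)
    })
    expect_lt(abs(mean(mi) - (a - 1) / (a + 1)), 0.03)
  }
})
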