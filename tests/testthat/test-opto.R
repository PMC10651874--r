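fake_opto_response <- function(delta, p, counts = rep(50, 20),
                               n_baseline = 100) {
  list(delta_hz = delta, p_per_bin = p, bin_edges = seq(0, 0.1, by = 0.005),
       counts_per_bin = counts, n_baseline_spikes = n_baseline,
       n_trials = 50)
}

test_that("delta FR is the post-light rate relative to the pre-light baseline", {
  on <- (1:50) * 3
  # one spike at +3 ms per trial, silent baseline
  d <- opto_delta_fr(spikes_at_offset(on, 0.003), on)
  expect_equal(d$delta_hz[1], 200)
  expect_equal(d$delta_hz[-1], rep(0, 19))
  expect_equal(d$counts_per_bin[1], 50)

  # unit silenced after light: 20 Hz baseline grid, nothing post-light
  pre <- as.vector(outer(on, seq(-0.0975, -0.0025, by = 0.005), "+"))
  d2 <- opto_delta_fr(sort(pre), on)
  expect_equal(d2$baseline_hz, 200)  # 1 spike per 5 ms bin
  expect_equal(d2$delta_hz, rep(-200, 20))
  expect_equal(d2$n_baseline_spikes, 50 * 20)
})

test_that("surrogate null is calibrated on a stationary unit", {
  set.seed(83)
  on <- 5 + (0:199) * 2.5
  T_end <- max(on) + 1
  sp <- sort(runif(rpois(1, 8 * T_end), 0, T_end))
  res <- opto_surrogate_null(sp, on, n_surrogates = 400, seed = 19)
  expect_length(res$null_delta_hz, 400 * 20)
  expect_true(all(res$p_per_bin > 0.001))
  # a deterministic response far above the null has p = 0
  res2 <- res
  res2$delta_hz[3] <- max(res$null_delta_hz) + 100
  p3 <- mean(res$null_delta_hz >= res2$delta_hz[3])
  expect_equal(p3, 0)

  # zero-spike unit: all deltas zero, nothing significant
  res0 <- opto_surrogate_null(numeric(0), on, n_surrogates = 50, seed = 3)
  expect_true(all(res0$delta_hz == 0))
  expect_true(all(res0$p_per_bin == 1))
})

test_that("surrogate p values are reproducible under a fixed seed", {
  set.seed(87)
  on <- 5 + (0:99) * 2.5
  sp <- sort(runif(2000, 0, max(on) + 1))
  r1 <- opto_surrogate_null(sp, on, n_surrogates = 200, seed = 11)
  r2 <- opto_surrogate_null(sp, on, n_surrogates = 200, seed = 11)
  expect_identical(r1$p_per_bin, r2$p_per_bin)
  expect_identical(r1$null_delta_hz, r2$null_delta_hz)
})

test_that("excitatory and inhibitory criteria follow the latency rules", {
  d <- rep(0, 20); p <- rep(1, 20)
  # first significant bin [0,5): latency 5 ms, excitatory
  d1 <- d; d1[1] <- 80; p1 <- p; p1[1] <- 0
  r <- classify_opto(fake_opto_response(d1, p1), mode = "terminal")
  expect_equal(r$label, "excitatory_short_latency")
  expect_equal(r$latency_ms, 5)
  # first significant bin [10,15): latency 15 ms fails the terminal cutoff
  d2 <- d; d2[3] <- 80; p2 <- p; p2[3] <- 0
  expect_equal(classify_opto(fake_opto_response(d2, p2),
                             mode = "terminal")$label, "none")
  # ... but passes the soma cutoff
  expect_equal(classify_opto(fake_opto_response(d2, p2),
                             mode = "soma")$label,
               "excitatory_short_latency")
  # spike-count guard: fewer than 10 spikes in the latency bin
  expect_equal(classify_opto(fake_opto_response(d1, p1, counts = rep(5, 20)),
                             mode = "terminal")$label, "none")
  # four consecutive suppressed bins at 15-35 ms with ample baseline spikes
  d3 <- d; d3[4:7] <- -10; p3 <- p; p3[4:7] <- 0.01
  expect_equal(classify_opto(fake_opto_response(d3, p3))$label, "inhibitory")
  # baseline-spike guard
  expect_equal(classify_opto(fake_opto_response(d3, p3,
                                                n_baseline = 10))$label,
               "none")
  # suppression outside the first 50 ms does not count
  d4 <- d; d4[12:15] <- -10; p4 <- p; p4[12:15] <- 0.01
  expect_equal(classify_opto(fake_opto_response(d4, p4))$label, "none")
  # excitation takes precedence over inhibition
  d5 <- d1; d5[4:7] <- -10; p5 <- p1; p5[4:7] <- 0.01
  expect_equal(classify_opto(fake_opto_response(d5, p5))$label,
               "excitatory_short_latency")
})

test_that("simulated opsin-positive sessions are mapped correctly", {
  cfg <- sim_config(seed = 91)
  cfg$opto$duration <- 400
  cfg$opto$fraction_excited <- 0.3
  cfg$opto$fraction_inhibited <- 0.1
  s <- generate_opto_session(cfg, opsin = TRUE, n_units = 25)
  ot <- opto_map_session(s, mode = "terminal", n_surrogates = 500, seed = 7)
  m <- merge(ot, s$units[, c("unit_id", "true_opto")])
  exc <- m$true_opto == "excited"
  expect_true(all(m$label[exc] == "excitatory_short_latency"))
  expect_true(all(m$latency_ms[exc] <= 10))
  expect_true(all(m$label[m$true_opto == "none"] != "excitatory_short_latency"))
})

test_that("population fractions reproduce printed layer ratios", {
  tab <- data.frame(
    depth_um = c(runif(194, 100, 599), runif(692, 600, 1100)),
    label = c(ifelse(seq_len(194) <= 9, "excitatory_short_latency", "none"),
              ifelse(seq_len(692) <= 54, "excitatory_short_latency", "none")))
  pf <- population_fractions(tab)
  expect_equal(pf$pct_excitatory[pf$layer == "upper"], 4.64)
  expect_equal(pf$pct_excitatory[pf$layer == "lower"], 7.80)
  pf0 <- population_fractions(data.frame(depth_um = c(200, 800),
                                         label = c("none", "none")))
  expect_equal(pf0$pct_excitatory, c(0, 0))
})
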