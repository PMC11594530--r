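# LFP proxy, multitaper spectra, band power, learner classification,
# rank-sum comparisons.

test_that("LFP proxy sums the recorded current components", {
  sim <- simulate_network(network_config(), "paired_2s", seed = 6)
  lin <- lfp_proxy(sim)
  expect_equal(lin$fs, 1000)
  comps <- c("ampa", "gaba", "d", "h", "nap")
  by_hand <- rowSums(sim$lfp[, comps])
  expect_equal(lin$x, by_hand)
  # rectified proxy dominates the linear one pointwise (triangle inequality)
  rec <- lfp_proxy(sim, mode = "rectified")
  expect_true(all(rec$x >= abs(lin$x) - 1e-12))
  # component restriction and transient discard
  ampa <- lfp_proxy(sim, components = "ampa", discard_transient = FALSE)
  expect_equal(ampa$x, sim$lfp$ampa)
  expect_error(lfp_proxy(sim, components = "nmda"), "unknown")
})

test_that("multitaper spectrum localises known signals", {
  t <- seq(0.001, 30, by = 0.001)
  psd <- multitaper_psd(sin(2 * pi * 4 * t), fs = 1000)
  expect_lt(abs(psd_peak(psd) - 4), 0.3)
  expect_true(all(psd$power >= 0))
  expect_true(all(diff(psd$freq) > 0))
  expect_true(min(psd$freq) >= 0.1 && max(psd$freq) <= 70)
  # white noise: approximately flat, level ~ 2 sigma^2 / fs (one-sided)
  set.seed(30)
  p2 <- multitaper_psd(rnorm(20000), fs = 1000)
  lo <- band_power(p2, 1, 30) / 29
  hi <- band_power(p2, 35, 64) / 29
  expect_lt(abs(lo / hi - 1), 0.15)
  expect_lt(abs(mean(p2$power) / 0.002 - 1), 0.15)
  # zero signal, degenerate input
  expect_equal(max(multitaper_psd(rep(0, 4000), fs = 1000,
                                  demean = FALSE)$power), 0)
  expect_error(multitaper_psd(rnorm(100), fs = 1000), "too short")
})

test_that("band power integrates the density and partitions exactly", {
  psd <- structure(data.frame(freq = seq(0.1, 70, by = 0.1), power = 0),
                   class = c("bla_psd", "data.frame"))
  expect_equal(band_power(psd, 2.5, 4), 0)
  t <- seq(0.001, 30, by = 0.001)
  p <- multitaper_psd(sin(2 * pi * 4 * t) + 0.01 * sin(2 * pi * 13 * t),
                      fs = 1000)
  expect_gt(band_power(p, 2.5, 4.5), 100 * band_power(p, 12, 14))
  parts <- band_power(p, 2.5, 4) + band_power(p, 4, 12) + band_power(p, 12, 14)
  expect_equal(parts, band_power(p, 2.5, 14), tolerance = 1e-12)
  expect_error(band_power(p, 4, 4), "empty band")
})

test_that("population rate signal conserves counts and shows rhythms", {
  none <- spike_rate_signal(list(numeric(0), numeric(0)), bin = 5,
                            t_range = c(0, 1000))
  expect_equal(none$total, 0)
  expect_true(all(none$x == 0))
  set.seed(44)
  spk <- list(sort(runif(300, 0, 5000)), sort(runif(200, 0, 5000)))
  srs <- spike_rate_signal(spk, bin = 5, t_range = c(0, 5000))
  expect_equal(srs$total, 500)
  expect_equal(mean(srs$x), 0, tolerance = 1e-12)
  # 4 Hz population bursting: 30 s of spikes clustered every 250 ms
  bursts <- unlist(lapply(seq(0, 29750, by = 250), function(t0)
    t0 + sort(runif(8, 0, 30))))
  p <- multitaper_psd(spike_rate_signal(list(bursts), bin = 5,
                                        t_range = c(0, 30000)))
  expect_lt(abs(psd_peak(p, 1, 8) - 4), 0.3)
})

test_that("learner classification applies the printed thresholds", {
  tr <- function(gvals, tmax) list(time = seq(0, tmax, length.out = length(gvals)),
                                   g = matrix(gvals, ncol = 1), post = "F1")
  expect_true(classify_learner(tr(seq(0, 0.15, length.out = 100), 40000),
                               "conditioning")$learner)
  expect_false(classify_learner(tr(rep(0, 100), 40000),
                                "conditioning")$learner)
  mid <- classify_learner(tr(seq(0, 0.12, length.out = 100), 45000),
                          "conditioning15_30")
  expect_true(mid$learner)  # g(15 s) = 0.04 > 0.037
  expect_equal(mid$threshold, 0.037)
  expect_error(classify_learner(tr(c(0, 0.1), 10000), "conditioning15_30"),
               "shorter")
})

test_that("rank-sum comparison matches exact small-sample behaviour", {
  same <- ranksum_compare(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_gt(same$p_value, 0.99)
  sep <- ranksum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)
  set.seed(2)
  big <- ranksum_compare(rnorm(20), rnorm(20) + 5)
  expect_lt(big$p_value, 0.001)
  expect_error(ranksum_compare(numeric(0), 1:3), "empty")
})
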