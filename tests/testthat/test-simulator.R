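# Network assembly, RK4 integration, determinism and spike detection.

test_that("assembled networks have the expected composition", {
  net <- assemble(network_config())
  expect_equal(nrow(net$roster), 7)  # 5 principal cells + 2 relays
  expect_equal(sum(net$edges$internal), 9)
  het <- assemble(network_config(heterogeneous = TRUE))
  pops <- table(het$roster$role)
  expect_equal(as.vector(pops[c("VIP", "SOM", "PV", "ECS", "F")]),
               c(3, 3, 3, 10, 10))
  # plastic pathway: every CS-receiving ECS to every US-receiving F
  pl <- het$edges[het$edges$plastic, ]
  expect_equal(nrow(pl), 25)
  abl <- assemble(network_config(ablate = "VIP"))
  expect_false(any(grepl("^VIP", abl$roster$label)))
  expect_false(any(grepl("^VIP", abl$edges$pre) |
                   grepl("^VIP", abl$edges$post)))
})

test_that("RK4 reproduces the closed-form solution of a leak-only membrane", {
  # with g_Na = g_K = 0 the cell is a linear RC circuit:
  #   V(t) = E_L + (V0 - E_L) exp(-g_L t / c_m),  tau = 10 ms
  cfg <- iso_cfg("F", noise = FALSE,
                 cell_overrides = list(F = list(g_na = 0, g_k = 0)),
                 iapp_override = list(F = 0))
  sim <- simulate_network(cfg, "baseline", duration = 10, seed = 8)
  v0 <- sim$V[1, 1]
  expected <- -67 + (v0 + 67) * exp(-0.1 * sim$time / 1)
  expect_lt(max(abs(sim$V[, 1] - expected) / abs(expected)), 1e-8)
})

test_that("a null vector field leaves the state unchanged", {
  cfg <- iso_cfg("F", noise = FALSE,
                 cell_overrides = list(F = list(g_na = 0, g_k = 0, g_l = 0)),
                 iapp_override = list(F = 0))
  sim <- simulate_network(cfg, "baseline", duration = 50, seed = 8)
  expect_equal(max(abs(diff(sim$V[, 1]))), 0)
})

test_that("simulations are bit-identical for a fixed (config, seed)", {
  cfg <- network_config()
  a <- simulate_network(cfg, "conditioning", duration = 2000, seed = 31)
  b <- simulate_network(cfg, "conditioning", duration = 2000, seed = 31)
  expect_identical(a$V, b$V)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$edges$g_final, b$edges$g_final)
  expect_identical(a$lfp, b$lfp)
  c <- simulate_network(cfg, "conditioning", duration = 2000, seed = 32)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("zero noise amplitude equals the noise-free trajectory", {
  ov <- list(VIP = list(noise_k = 0), SOM = list(noise_k = 0),
             PV = list(noise_k = 0), ECS = list(noise_k = 0),
             F = list(noise_k = 0), AUX = list(noise_k = 0))
  cfg_amp0 <- network_config(noise = TRUE, cell_overrides = ov)
  cfg_off <- network_config(noise = FALSE)
  a <- simulate_network(cfg_amp0, "conditioning", duration = 1000, seed = 12)
  b <- simulate_network(cfg_off, "conditioning", duration = 1000, seed = 12)
  expect_identical(a$V, b$V)
})

test_that("halving the step barely changes a noise-free trajectory", {
  # subthreshold dynamics: trace-level agreement
  mk <- function(dt) network_config(populations = c(VIP = 0, SOM = 0, PV = 1,
                                                    ECS = 0, F = 0),
                                    include_synapses = FALSE,
                                    include_stimulus = FALSE,
                                    noise = FALSE, dt = dt)
  pa <- simulate_network(mk(0.05), "baseline", duration = 500, seed = 9)
  pb <- simulate_network(mk(0.025), "baseline", duration = 500, seed = 9)
  expect_lt(max(abs(pa$V - pb$V)), 1e-6)
  # spiking network: identical spike counts, sub-millisecond timing shifts
  cfg1 <- network_config(noise = FALSE)
  cfg2 <- network_config(noise = FALSE, dt = 0.025)
  a <- simulate_network(cfg1, "conditioning", duration = 500, seed = 14)
  b <- simulate_network(cfg2, "conditioning", duration = 500, seed = 14)
  expect_equal(lengths(a$spikes), lengths(b$spikes))
  for (cell in names(a$spikes)) {
    if (length(a$spikes[[cell]]) > 0)
      expect_lt(max(abs(a$spikes[[cell]] - b$spikes[[cell]])), 1)
  }
})

test_that("voltages stay within physiological bounds", {
  sim <- simulate_network(network_config(heterogeneous = TRUE),
                          "conditioning", duration = 3000, seed = 15)
  expect_true(all(sim$V >= -120 & sim$V <= 60))
})

test_that("spike detection finds threshold crossings with refractoriness", {
  t <- seq(0, 1000, by = 0.05)
  expect_length(detect_spikes(rep(-70, length(t)), t), 0)
  one <- -70 + 90 * exp(-(t - 500)^2 / 4)
  expect_length(detect_spikes(one, t), 1)
  # synthetic 40 Hz spike train: 2 ms triangular spikes every 25 ms
  v <- rep(-70, length(t))
  for (tc in seq(10, 990, by = 25)) v[abs(t - tc) < 1] <- 20
  s <- detect_spikes(v, t)
  expect_equal(length(s), 40)
  expect_true(all(abs(diff(s) - 25) < 0.2))
})

test_that("reciprocal F-PV pair locks into gamma with F leading (PING)", {
  cfg <- network_config(populations = c(VIP = 0, SOM = 0, PV = 1, ECS = 0,
                                        F = 1),
                        include_stimulus = FALSE,
                        iapp_override = list(F = 2))
  sim <- simulate_network(cfg, "baseline", duration = 4000, seed = 21)
  f <- sim$spikes[["F1"]]
  pv <- sim$spikes[["PV1"]]
  f <- f[f > 1000]
  pv <- pv[pv > 1000]
  expect_gt(length(f) / 3, 30)   # both above gamma floor
  expect_gt(length(pv) / 3, 30)
  # each PV spike trails an F spike within a fraction of the gamma cycle
  lead <- vapply(pv, function(s) {
    prev <- f[f < s]
    if (length(prev) == 0) NA_real_ else s - max(prev)
  }, numeric(1))
  expect_gt(mean(lead < 5, na.rm = TRUE), 0.8)
  expect_gt(median(lead, na.rm = TRUE), 0)
})

test_that("simulation results carry consistent structure", {
  sim <- simulate_network(network_config(), "paired_2s", seed = 2)
  expect_s3_class(sim, "bla_sim")
  expect_equal(sim$duration, 2000)
  expect_equal(colnames(sim$V), sim$roster$label)
  expect_true(all(vapply(sim$spikes, function(s) all(diff(s) > 0), TRUE)))
  expect_equal(sim$transient_ms, 2000)
  # conductance trajectory recorded on the 1 ms grid, starts at zero
  expect_equal(unname(sim$g$g[1, 1]), 0)
  expect_equal(nrow(sim$g$g), 2001)
})
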