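# Hodgkin-Huxley cell types: rate functions, currents, gating dynamics.

test_that("steady states and time constants match the printed kinetics", {
  # sigmoid midpoints and fixed time constants
  expect_equal(steady_state_and_tau("VIP", "m", -24)$x_inf, 0.5)
  a <- steady_state_and_tau("VIP", "a", -50)
  expect_equal(a$x_inf, 0.5)
  expect_equal(a$tau, 2)
  b <- steady_state_and_tau("VIP", "b", -70)
  expect_equal(b$x_inf, 0.5)
  expect_equal(b$tau, 150)
  p <- steady_state_and_tau("SOM", "p", -38)
  expect_equal(p$x_inf, 0.5)
  expect_equal(p$tau, 0.15)
  expect_equal(steady_state_and_tau("SOM", "hf", -79.2)$x_inf, 0.5)
  # alpha/beta channels: x_inf in [0,1], tau > 0 over a wide voltage range
  for (ct in c("SOM", "PV", "E")) {
    for (ch in setdiff(blafear:::GATES[[ct]], "m")) {
      for (v in seq(-110, 40, by = 10)) {
        st <- steady_state_and_tau(ct, ch, v)
        expect_true(st$x_inf >= 0 && st$x_inf <= 1)
        expect_true(st$tau > 0)
      }
    }
  }
  # removable singularities are finite and smooth (PV alpha_m at V = -54)
  near <- vapply(c(-54 - 1e-7, -54, -54 + 1e-7), function(v)
    steady_state_and_tau("PV", "m", v)$x_inf, numeric(1))
  expect_true(all(is.finite(near)))
  expect_lt(diff(range(near)), 1e-6)
  expect_error(steady_state_and_tau("PV", "a", -50), "not defined")
  expect_error(steady_state_and_tau("bogus", "m", 0), "cell_type")
})

test_that("membrane currents vanish at their reversal potentials", {
  g_pv <- gating_steady_state("PV", -67)
  expect_equal(membrane_currents("PV", -67, g_pv)[["L"]], 0)
  g_som <- gating_steady_state("SOM", -20)
  g_som["hf"] <- 1
  g_som["hs"] <- 1
  expect_equal(membrane_currents("SOM", -20, g_som)[["H"]], 0)
  g_vip <- gating_steady_state("VIP", -50)
  g_vip["a"] <- 0
  g_vip["b"] <- 1
  expect_equal(membrane_currents("VIP", -50, g_vip)[["D"]], 0)
  # channel sets per type
  expect_named(membrane_currents("VIP", -60, gating_steady_state("VIP", -60)),
               c("Na", "K", "L", "D"))
  expect_named(membrane_currents("SOM", -60, gating_steady_state("SOM", -60)),
               c("Na", "K", "L", "H", "P"))
  expect_named(membrane_currents("E", -60, gating_steady_state("E", -60)),
               c("Na", "K", "L"))
  expect_error(membrane_currents("PV", -60, c(m = 1.5, h = 0, n = 0)),
               "\\[0, 1\\]")
})

test_that("gating derivatives vanish at the fixed point and stay bounded", {
  set.seed(7)
  for (ct in names(blafear:::GATES)) {
    for (v in runif(5, -90, 0)) {
      d <- gating_derivatives(ct, v, gating_steady_state(ct, v))
      expect_equal(unname(d), rep(0, length(d)), tolerance = 1e-12)
    }
    # forward-integrate under a random voltage schedule: gates stay in [0,1]
    g <- gating_steady_state(ct, -65)
    for (step in 1:400) {
      v <- runif(1, -100, 30)
      g[] <- pmin(1, pmax(0, g + 0.05 * gating_derivatives(ct, v, g)))
      expect_true(all(g >= 0 & g <= 1))
    }
  }
  # printed example: b relaxation at -70 mV from b = 0
  d <- gating_derivatives("VIP", -70,
                          replace(gating_steady_state("VIP", -70), "b", 0))
  expect_equal(d[["b"]], 0.5 / 150)
})

test_that("parameter table is validated and overridable", {
  tab <- load_cell_params()
  expect_setequal(tab$cell_type, c("VIP", "SOM", "PV", "E"))
  expect_equal(cell_params("VIP")$g_d, 3)
  expect_equal(cell_params("SOM")$g_h, 1.45)
  expect_equal(cell_params("E", g_na = 0)$g_na, 0)
  expect_error(cell_params("E", bogus = 1), "unknown parameter")
  # loader rejects tables violating the per-type channel structure
  bad <- tab
  bad$g_d[bad$cell_type == "PV"] <- 1
  tmp <- tempfile(fileext = ".csv")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_cell_params(tmp), "VIP-specific")
})

test_that("PV cells are quiescent at baseline and settle to rest", {
  cfg <- iso_cfg("PV", noise = FALSE)
  sim <- simulate_network(cfg, "baseline", duration = 10000, seed = 3)
  expect_length(sim$spikes[[1]], 0)
  tail_v <- sim$V[sim$time > 9000, 1]
  expect_lt(diff(range(tail_v)), 2)
})

test_that("E-cell firing rate is monotone nondecreasing in applied current", {
  rates <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(i) {
    cfg <- iso_cfg("F", noise = FALSE, iapp_override = list(F = i))
    sim <- simulate_network(cfg, "baseline", duration = 5000, seed = 4)
    length(sim$spikes[[1]]) / 5
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
  expect_gt(rates[5], rates[2])
})
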