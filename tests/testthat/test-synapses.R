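# GABAa/AMPA kinetics and connectivity construction.

test_that("open rates follow the presynaptic-type-specific forms", {
  expect_equal(presynaptic_open_rate("PV", 0), 7.5)
  expect_equal(presynaptic_open_rate("E", 0), 5)
  expect_equal(presynaptic_open_rate("SOM", 0), 2.5)
  expect_equal(presynaptic_open_rate("VIP", 0), 2)
  # tanh saturation
  expect_equal(presynaptic_open_rate("VIP", 100), 4, tolerance = 1e-12)
  expect_equal(presynaptic_open_rate("E", -100), 0, tolerance = 1e-12)
  v <- seq(-100, 60, by = 2.5)
  for (ty in c("VIP", "PV", "SOM", "E")) {
    r <- presynaptic_open_rate(ty, v)
    expect_true(all(r >= 0))
    expect_true(all(diff(r) >= -1e-12))  # monotone in presynaptic voltage
  }
})

test_that("gate derivative has the printed form and keeps s in [0, 1]", {
  expect_equal(synapse_gate_derivative("PV", s = 1, v_pre = -90), -1 / 8.3)
  expect_equal(synapse_gate_derivative("SOM", s = 1, v_pre = -90), -1 / 20)
  expect_equal(synapse_gate_derivative("PV", s = 0, v_pre = -90), 0,
               tolerance = 1e-10)
  expect_equal(synapse_gate_derivative("PV", s = 0, v_pre = 0), 7.5)
  # bounded under integration against an arbitrary presynaptic trace
  set.seed(11)
  s <- 0.5
  for (i in 1:2000) {
    s <- s + 0.05 * synapse_gate_derivative("PV", s, runif(1, -90, 40))
    expect_true(s >= 0 && s <= 1)
  }
  # silent presynaptic cell: s decays below 1e-3 within 10 tau
  s <- 1
  tau <- synapse_kinetics("VIP")$tau_decay
  for (i in seq_len(10 * tau / 0.05)) {
    s <- s + 0.05 * synapse_gate_derivative("VIP", s, -62)
  }
  expect_lt(s, 1e-3)
})

test_that("synaptic currents vanish at reversal and follow g s (V - E)", {
  expect_equal(synaptic_current(0.7, 0.9, -80, e_rev = -80), 0)
  expect_equal(synaptic_current(0.2, 0.3, 0, e_rev = 0), 0)
  expect_equal(synaptic_current(0.5, 1, -60, e_rev = -80), 10)
  expect_error(synaptic_current(0.5, 1.4, -60, -80))
})

test_that("connectivity has the nine projections with printed scalings", {
  cfg <- network_config(include_stimulus = FALSE)
  edges <- build_connectivity(cfg)
  expect_equal(nrow(edges), 9)
  proj <- paste(edges$pre, edges$post, sep = "->")
  expect_setequal(proj, c("VIP1->PV1", "VIP1->SOM1", "PV1->F1", "PV1->ECS1",
                          "SOM1->F1", "SOM1->ECS1", "ECS1->F1", "F1->PV1",
                          "F1->VIP1"))
  # no cross-inhibition among PV/SOM/VIP beyond VIP->PV, VIP->SOM
  expect_false(any(grepl("^PV", edges$pre) & grepl("^(SOM|VIP)", edges$post)))
  expect_false(any(grepl("^SOM", edges$pre) & grepl("^(PV|VIP)", edges$post)))
  # GABAa/AMPA constants by presynaptic type
  gab <- edges[edges$kind == "GABAa", ]
  expect_true(all(gab$e_rev == -80))
  expect_equal(sort(unique(gab$tau_decay)), c(8.3, 10, 20))
  amp <- edges[edges$kind == "AMPA", ]
  expect_true(all(amp$e_rev == 0 & amp$tau_decay == 2))
  # plastic pathway starts silent with the printed ceiling
  ecsf <- edges[edges$pre == "ECS1" & edges$post == "F1", ]
  expect_equal(ecsf$g, 0)
  expect_true(ecsf$plastic)
  expect_equal(ecsf$g_max, 0.18)
  expect_equal(edges$g[proj == "F1->PV1"], 0.5)
  expect_equal(edges$g[proj == "F1->VIP1"], 0.01)
})

test_that("inhibitory conductances scale with population size", {
  cfg <- network_config(populations = c(VIP = 3, SOM = 2, PV = 2, ECS = 1,
                                        F = 1))
  edges <- build_connectivity(cfg)
  vip_pv <- edges[grepl("^VIP", edges$pre) & grepl("^PV", edges$post), ]
  expect_equal(nrow(vip_pv), 6)
  expect_true(all(vip_pv$g == 1 / 3))
  # printed VIP->SOM scaling divides by the postsynaptic SOM count
  vip_som <- edges[grepl("^VIP", edges$pre) & grepl("^SOM", edges$post), ]
  expect_true(all(vip_som$g == 1 / 2))
  # the pre-scaling variant divides by the VIP count instead
  cfg2 <- network_config(populations = c(VIP = 3, SOM = 2, PV = 2, ECS = 1,
                                         F = 1), scale_by = "pre")
  e2 <- build_connectivity(cfg2)
  vs2 <- e2[grepl("^VIP", e2$pre) & grepl("^SOM", e2$post), ]
  expect_true(all(vs2$g == 1 / 3))
  expect_error(network_config(populations = c(VIP = -1, SOM = 1, PV = 1,
                                              ECS = 1, F = 1)), "nonnegative")
})

test_that("ablation removes cells and their synapses", {
  cfg <- network_config(ablate = "VIP")
  edges <- build_connectivity(cfg)
  expect_false(any(grepl("^VIP", edges$pre) | grepl("^VIP", edges$post)))
  expect_equal(nrow(edges), 6)
  expect_error(network_config(ablate = "F"), "cannot ablate")
})
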