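# Depression-dominated trace STDP on the CS->fear pathway.

test_that("trace decay is exponential with the printed time constants", {
  st <- plasticity_state(p = 0.005, m = -0.003, g = 0.1)
  out <- decay_traces(st, 14)
  expect_equal(out$p, 0.005 * exp(-1))
  expect_equal(out$m, -0.003 * exp(-14 / 28))
  expect_equal(out$g, 0.1)
  expect_identical(decay_traces(st, 0), st)
  zero <- plasticity_state()
  expect_identical(decay_traces(zero, 123), zero)
  expect_error(decay_traces(st, -1), "nonnegative")
})

test_that("spike updates weaken/strengthen with clipping", {
  rule <- stdp_rule()
  # presynaptic spike: weakening by M (floor 0), then P increment
  st <- on_pre_spike(plasticity_state(m = 0, g = 0.05), rule)
  expect_equal(st$g, 0.05)
  expect_equal(st$p, 0.005)
  expect_equal(on_pre_spike(plasticity_state(m = -0.1, g = 0.05), rule)$g, 0)
  expect_equal(on_pre_spike(plasticity_state(m = -0.002, g = 0.05), rule)$g,
               0.048)
  # postsynaptic spike: strengthening by P (ceiling g_max), then M decrement
  st <- on_post_spike(plasticity_state(p = 0, g = 0.05), rule)
  expect_equal(st$g, 0.05)
  expect_equal(st$m, -0.005)
  expect_equal(on_post_spike(plasticity_state(p = 0.2, g = 0.1), rule)$g, 0.18)
  # pre at t=0 then post at t=5: potentiation by A+ exp(-5/tau+)
  st <- on_pre_spike(plasticity_state(g = 0.05), rule)
  st <- decay_traces(st, 5, rule)
  st <- on_post_spike(st, rule)
  expect_equal(st$g - 0.05, 0.005 * exp(-5 / 14))
  orc <- stdp_event_oracle(pre_times = 1, post_times = 6, g0 = 0.05)
  expect_equal(st$g, orc$g)
})

test_that("clock-driven evolution matches the event-driven oracle", {
  set.seed(42)
  for (rep in 1:5) {
    pre <- grid_poisson(25, 2000)
    post <- grid_poisson(25, 2000)
    clock <- stdp_apply_clock(pre, post, duration = 2000, g0 = 0.09)
    orc <- stdp_event_oracle(pre, post, g0 = 0.09)
    expect_equal(clock$state$g, orc$g, tolerance = 1e-9)
    # conductance never leaves [0, g_max]
    expect_true(all(clock$g >= 0 & clock$g <= 0.18))
  }
})

test_that("conductance stays within [0, g_max] under adversarial trains", {
  set.seed(9)
  # bursty, overlapping, high-rate trains hammering both clips
  pre <- grid_poisson(200, 1000)
  post <- grid_poisson(200, 1000)
  out <- stdp_apply_clock(pre, post, duration = 1000, g0 = 0.18)
  expect_true(all(out$g >= 0 & out$g <= 0.18))
  out0 <- stdp_apply_clock(pre, numeric(0), duration = 1000, g0 = 0.001)
  expect_true(all(out0$g >= 0))
})

test_that("expected drift is negative for the depression-dominated rule", {
  rule <- stdp_rule()
  # A+ tau+ - A- tau- = 0.005*14 - 0.005*28 < 0
  expect_equal(expected_drift(rule, 20, 20), 20 * 20 * (-0.07) / 1000)
  expect_lt(expected_drift(rule, 20, 20), 0)
  expect_equal(expected_drift(rule, 0, 20), 0)
  balanced <- stdp_rule(tau_plus = 28)
  expect_equal(expected_drift(balanced, 20, 20), 0)
  # F->VIP variant is not depression-dominated
  fv <- stdp_rule_f_vip()
  expect_gt(fv$a_plus * fv$tau_plus, fv$a_minus * fv$tau_minus)
  expect_gt(expected_drift(fv, 20, 20), 0)
})

test_that("Monte-Carlo drift under independent Poisson trains matches theory", {
  set.seed(123)
  run_drift <- function(rule) {
    mean(vapply(1:24, function(i) {
      pre <- grid_poisson(20, 10000)
      post <- grid_poisson(20, 10000)
      stdp_apply_clock(pre, post, duration = 10000, g0 = 0.09,
                       rule = rule)$state$g - 0.09
    }, numeric(1)))
  }
  # depression-dominated: mean final conductance below the initial value
  expect_lt(run_drift(stdp_rule()), 0)
  # classical Hebbian configuration (A+ tau+ > A- tau-): positive drift
  hebb <- stdp_rule(tau_plus = 28, tau_minus = 14)
  expect_gt(run_drift(hebb), 0)
})
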