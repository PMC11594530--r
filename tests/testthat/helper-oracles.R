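# Independent oracles used across the test files.

# Event-driven STDP evolution: exact exponential decay between events,
# written directly from the update rules (independent of the package's
# clock-driven loop).
stdp_event_oracle <- function(pre_times, post_times, g0 = 0,
                              a_plus = 0.005, a_minus = 0.005,
                              tau_plus = 14, tau_minus = 28, g_max = 0.18) {
  ev <- rbind(
    data.frame(t = pre_times, kind = 0),
    data.frame(t = post_times, kind = 1)
  )
  ev <- ev[order(ev$t, ev$kind), , drop = FALSE]  # pre before post at ties
  p <- 0; m <- 0; g <- g0; t_last <- 0
  for (i in seq_len(nrow(ev))) {
    dt <- ev$t[i] - t_last
    p <- p * exp(-dt / tau_plus)
    m <- m * exp(-dt / tau_minus)
    t_last <- ev$t[i]
    if (ev$kind[i] == 0) {
      g <- max(0, g + m)
      p <- p + a_plus
    } else {
      g <- min(g_max, g + p)
      m <- m - a_minus
    }
  }
  list(g = g, p = p, m = m)
}

# Poisson spike train snapped to an integration grid (unique steps)
grid_poisson <- function(rate_hz, duration_ms, dt = 0.05) {
  n <- rpois(1, rate_hz * duration_ms / 1000)
  t <- sort(runif(n, 0, duration_ms))
  t <- round(t / dt) * dt
  unique(t[t > 0])
}

# single-cell isolated configuration helper
iso_cfg <- function(role, ...) {
  pops <- c(VIP = 0, SOM = 0, PV = 0, ECS = 0, F = 0)
  pops[[role]] <- 1
  network_config(populations = pops, include_synapses = FALSE,
                 include_stimulus = FALSE, ...)
}
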