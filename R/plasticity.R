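# Trace-based spike-timing-dependent plasticity on the CS->fear pathway.
#
# Two auxiliary traces accumulate over the whole spike history: P (incremented
# at presynaptic spikes, drives strengthening at postsynaptic spikes) and M
# (decremented at postsynaptic spikes, drives weakening at presynaptic
# spikes). With equal amplitudes and a longer depression time constant the
# rule is depression-dominated: potentiation requires fine pre-before-post
# timing plus pauses during which the accumulated depression decays away.

#' STDP rule constants
#'
#' The default is the depression-dominated pair rule used on the ECS->F
#' synapse: equal amplitudes `A+ = A- = 0.005` with `tau+ = 14 ms <
#' tau- = 28 ms`, conductance clipped to `[0, g_max]` with
#' `g_max = 0.18 mS/cm^2`.
#'
#' @param a_plus,a_minus trace increments per spike (dimensionless).
#' @param tau_plus,tau_minus trace decay constants (ms).
#' @param g_max conductance ceiling (mS/cm^2).
#' @return list of class "stdp_rule".
#' @export
stdp_rule <- function(a_plus = 0.005, a_minus = 0.005,
                      tau_plus = 14, tau_minus = 28, g_max = 0.18) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0, g_max > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, g_max = g_max), class = "stdp_rule")
}

#' Rule constants for the plastic F->VIP variant
#'
#' `A+ = 0.00065`, `A- = 0.0003` with the standard time constants; since
#' `A+ tau+ > A- tau-` this variant is not depression-dominated.
#' @export
stdp_rule_f_vip <- function() {
  stdp_rule(a_plus = 0.00065, a_minus = 0.0003, g_max = 0.04)
}

#' Plasticity state of one synapse
#'
#' @param p potentiation trace (>= 0).
#' @param m depression trace (<= 0).
#' @param g current plastic conductance (mS/cm^2).
#' @export
plasticity_state <- function(p = 0, m = 0, g = 0) {
  stopifnot(p >= 0, m <= 0, g >= 0)
  list(p = p, m = m, g = g)
}

#' Decay the plasticity traces over an interval
#'
#' Both traces relax exponentially to zero between spikes
#' (`tau+ dP/dt = -P`, `tau- dM/dt = -M`); the conductance is untouched.
#'
#' @param state a [plasticity_state()].
#' @param dt elapsed time (ms, >= 0).
#' @param rule an [stdp_rule()].
#' @export
decay_traces <- function(state, dt, rule = stdp_rule()) {
  if (dt < 0) stop("dt must be nonnegative")
  state$p <- state$p * exp(-dt / rule$tau_plus)
  state$m <- state$m * exp(-dt / rule$tau_minus)
  state
}

#' Apply a presynaptic (ECS) spike
#'
#' The synapse is weakened by the current depression trace
#' (`g <- max(0, g + M)`, floor at zero), then the potentiation trace is
#' incremented by `A+`. Traces must already be decayed to the spike time.
#'
#' @inheritParams decay_traces
#' @export
on_pre_spike <- function(state, rule = stdp_rule()) {
  state$g <- max(0, state$g + state$m)
  state$p <- state$p + rule$a_plus
  state
}

#' Apply a postsynaptic (F) spike
#'
#' The synapse is strengthened by the current potentiation trace
#' (`g <- min(g_max, g + P)`, ceiling at `g_max`), then the depression trace
#' is decremented by `A-`.
#'
#' @inheritParams decay_traces
#' @export
on_post_spike <- function(state, rule = stdp_rule()) {
  state$g <- min(rule$g_max, state$g + state$p)
  state$m <- state$m - rule$a_minus
  state
}

#' Expected conductance drift under independent Poisson firing
#'
#' For stationary independent pre/post Poisson trains (no clipping), the mean
#' drift of the plastic conductance is
#' `rate_pre * rate_post * (A+ tau+ - A- tau-)`, returned in mS/cm^2 per
#' second with rates in Hz. Strictly negative for the depression-dominated
#' default; zero at the balance point `A+ tau+ = A- tau-`.
#'
#' @param rule an [stdp_rule()].
#' @param rate_pre,rate_post firing rates (Hz).
#' @export
expected_drift <- function(rule, rate_pre, rate_post) {
  rate_pre * rate_post *
    (rule$a_plus * rule$tau_plus - rule$a_minus * rule$tau_minus) / 1000
}

#' Evolve a plastic synapse over fixed spike trains
#'
#' Clock-driven update identical to the simulator's inner loop: traces decay
#' by one step factor per grid step and spikes (assumed on grid points) are
#' applied at the step on which they fall, presynaptic updates before
#' postsynaptic ones. Useful for validating the rule against event-driven
#' computations.
#'
#' @param pre_times,post_times spike times (ms), nondecreasing.
#' @param duration total time (ms).
#' @param dt grid step (ms).
#' @param g0 initial conductance (mS/cm^2).
#' @param rule an [stdp_rule()].
#' @return list with the final `state` and the conductance trajectory
#'   sampled every step (`time`, `g`).
#' @export
stdp_apply_clock <- function(pre_times, post_times, duration, dt = 0.05,
                             g0 = 0, rule = stdp_rule()) {
  n_steps <- round(duration / dt)
  fp <- exp(-dt / rule$tau_plus)
  fm <- exp(-dt / rule$tau_minus)
  state <- plasticity_state(g = g0)
  pre_at <- tabulate(round(pre_times / dt), nbins = n_steps)
  post_at <- tabulate(round(post_times / dt), nbins = n_steps)
  gtraj <- numeric(n_steps + 1)
  gtraj[1] <- g0
  for (step in seq_len(n_steps)) {
    state$p <- state$p * fp
    state$m <- state$m * fm
    if (pre_at[step] > 0)
      for (k in seq_len(pre_at[step])) state <- on_pre_spike(state, rule)
    if (post_at[step] > 0)
      for (k in seq_len(post_at[step])) state <- on_post_spike(state, rule)
    gtraj[step + 1] <- state$g
  }
  list(state = state, time = seq(0, by = dt, length.out = n_steps + 1),
       g = gtraj)
}
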