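# Network assembly and integration: RK4 at dt = 0.05 ms with additive
# per-step Gaussian noise, online spike detection, STDP events, and trace
# recording (voltages, spikes, LFP current components, plastic conductances).

#' Network configuration
#'
#' @param populations named counts for VIP, SOM, PV, ECS and F. Defaults to
#'   one cell of each type, or 3/3/3/10/10 when `heterogeneous = TRUE`.
#'   A zero entry removes the population.
#' @param heterogeneous use the multi-cell network with per-cell parameter
#'   jitter and independent noise streams.
#' @param ablate subset of `c("VIP", "SOM", "PV")` removed together with all
#'   their synapses.
#' @param n_cs_ecs,n_us_f number of ECS cells receiving the CS relay drive and
#'   of F cells receiving the US relay drive (defaults: all in the single-cell
#'   network, 5 of 10 in the heterogeneous network; the remainder are
#'   unresponsive cells kept for the LFP).
#' @param scale_by `"printed"` scales the VIP->SOM conductance by the
#'   postsynaptic SOM count as printed; `"pre"` uses the presynaptic VIP
#'   count for symmetry with VIP->PV.
#' @param scale_excitatory `"printed"` uses the printed excitatory
#'   conductances and plastic ceiling verbatim on every synapse;
#'   `"active"` divides them by the number of stimulus-receiving
#'   presynaptic cells so each target's total drive matches the single-cell
#'   circuit.
#' @param stdp plasticity rule for the ECS->F pathway ([stdp_rule()]).
#' @param plastic_f_vip make the F->VIP synapses plastic with
#'   [stdp_rule_f_vip()] constants.
#' @param stimulus a [stimulus_config()].
#' @param include_synapses drop all internal synapses when `FALSE` (isolated
#'   or drive-calibration runs).
#' @param include_stimulus attach the auxiliary relay cells and Poisson
#'   units; `FALSE` for isolated-cell scans.
#' @param noise enable the additive Gaussian noise current.
#' @param noise_scaling interpretation of the stated noise amplitudes
#'   (k = 5 for VIP, 4 otherwise, times a power of the step): `"sqrt"`
#'   (default) uses the dt-invariant Euler-Maruyama scaling `k * sqrt(dt)`,
#'   under which the VIP burst statistics land on their stated values;
#'   `"printed"` uses the literal per-step amplitude `k * dt`.
#' @param iapp_jitter half-width of the multiplicative uniform jitter applied
#'   to each cell's background current in heterogeneous networks.
#' @param iapp_override named list (by role) of constant background currents
#'   replacing the defaults, e.g. `list(F = 1.2)` to drive a PING motif.
#' @param cell_overrides named list (by role) of cell-parameter overrides
#'   passed to [cell_params()].
#' @param dt integration step (ms).
#' @return list of class "bla_config".
#' @export
network_config <- function(populations = NULL, heterogeneous = FALSE,
                           ablate = character(),
                           n_cs_ecs = NULL, n_us_f = NULL,
                           scale_by = c("printed", "pre"),
                           scale_excitatory = c("active", "printed"),
                           stdp = stdp_rule(), plastic_f_vip = FALSE,
                           stimulus = stimulus_config(),
                           include_synapses = TRUE, include_stimulus = TRUE,
                           noise = TRUE,
                           noise_scaling = c("sqrt", "printed"),
                           iapp_jitter = if (heterogeneous) 0.05 else 0,
                           iapp_override = NULL, cell_overrides = NULL,
                           dt = 0.05) {
  if (is.null(populations)) {
    populations <- if (heterogeneous) c(VIP = 3, SOM = 3, PV = 3, ECS = 10, F = 10)
                   else c(VIP = 1, SOM = 1, PV = 1, ECS = 1, F = 1)
  }
  roles <- c("VIP", "SOM", "PV", "ECS", "F")
  if (!all(roles %in% names(populations)))
    stop("populations must name ", paste(roles, collapse = ", "))
  populations <- populations[roles]
  if (any(populations < 0)) stop("population sizes must be nonnegative")
  bad <- setdiff(ablate, c("VIP", "SOM", "PV"))
  if (length(bad) > 0) stop("cannot ablate: ", paste(bad, collapse = ", "))
  populations[ablate] <- 0
  if (is.null(n_cs_ecs))
    n_cs_ecs <- if (heterogeneous) min(5, populations[["ECS"]]) else populations[["ECS"]]
  if (is.null(n_us_f))
    n_us_f <- if (heterogeneous) min(5, populations[["F"]]) else populations[["F"]]
  stopifnot(n_cs_ecs <= populations[["ECS"]], n_us_f <= populations[["F"]])
  structure(list(
    populations = populations, heterogeneous = heterogeneous, ablate = ablate,
    n_cs_ecs = n_cs_ecs, n_us_f = n_us_f, scale_by = match.arg(scale_by),
    scale_excitatory = match.arg(scale_excitatory),
    stdp = stdp, plastic_f_vip = plastic_f_vip,
    stdp_f_vip = stdp_rule_f_vip(), stimulus = stimulus,
    include_synapses = include_synapses, include_stimulus = include_stimulus,
    noise = noise, noise_scaling = match.arg(noise_scaling),
    iapp_jitter = iapp_jitter, iapp_override = iapp_override,
    cell_overrides = cell_overrides, dt = dt), class = "bla_config")
}

#' Cell roster of a configured network
#'
#' @param config a [network_config()].
#' @return data.frame with one row per cell: `id`, `label`, `role`,
#'   `type` (HH cell type), `cs_target`, `us_target`.
#' @export
network_roster <- function(config) {
  n <- config$populations
  rows <- list()
  type_of <- c(VIP = "VIP", SOM = "SOM", PV = "PV", ECS = "E", F = "E")
  for (role in names(n)) {
    if (n[[role]] == 0) next
    k <- seq_len(n[[role]])
    rows[[role]] <- data.frame(
      label = paste0(role, k), role = role, type = type_of[[role]],
      cs_target = role == "ECS" & k <= config$n_cs_ecs,
      us_target = role == "F" & k <= config$n_us_f,
      stringsAsFactors = FALSE)
  }
  if (config$include_stimulus) {
    rows[["AUX"]] <- data.frame(
      label = c("AUX_CS", "AUX_US"), role = "AUX", type = "E",
      cs_target = FALSE, us_target = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$id <- seq_len(nrow(out))
  out[, c("id", "label", "role", "type", "cs_target", "us_target")]
}

#' Assemble a network from a configuration
#'
#' Builds the roster, the internal connectivity and the stimulus wiring.
#'
#' @param config a [network_config()].
#' @return list of class "bla_network" with `roster`, `edges` (internal +
#'   relay drive, with an `internal` flag) and `config`.
#' @export
assemble <- function(config) {
  if (!inherits(config, "bla_config")) stop("config must be a network_config()")
  roster <- network_roster(config)
  edges <- NULL
  if (config$include_synapses) {
    edges <- build_connectivity(config)
    if (!is.null(edges)) edges$internal <- TRUE
  }
  if (config$include_stimulus) {
    aux_edges <- build_stimulus_network(config)
    if (!is.null(aux_edges) && nrow(aux_edges) > 0) {
      aux_edges$internal <- FALSE
      edges <- if (is.null(edges)) aux_edges else rbind(edges, aux_edges)
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(pre = character(0), post = character(0),
                        pre_id = integer(0), post_id = integer(0),
                        kind = character(0), g = numeric(0),
                        e_rev = numeric(0), tau_decay = numeric(0),
                        plastic = logical(0), g_max = numeric(0),
                        internal = logical(0))
  }
  structure(list(roster = roster, edges = edges, config = config),
            class = "bla_network")
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a threshold separated by at least a refractory
#' interval.
#'
#' @param v voltage trace (mV) on a uniform grid.
#' @param times sample times (ms), or a scalar step if `length(v) > 2`.
#' @param threshold crossing threshold (mV).
#' @param refractory minimum separation (ms).
#' @return spike times (ms).
#' @export
detect_spikes <- function(v, times, threshold = 0, refractory = 2) {
  if (length(times) == 1) times <- seq(0, by = times, length.out = length(v))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  out <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (times[i] - last >= refractory) {
      out <- c(out, times[i])
      last <- times[i]
    }
  }
  out
}

# role of each cell for the applied-current rules
.roster_iapp <- function(roster, phases, config, jitter) {
  over <- config$iapp_override
  sapply(seq_len(nrow(roster)), function(i) {
    role <- roster$role[i]
    base <- vapply(seq_len(nrow(phases)), function(p) {
      if (!is.null(over) && !is.null(over[[role]])) return(over[[role]])
      ph1 <- phases[p, , drop = FALSE]
      # US-phase current bumps apply to the targeted cells: all VIP cells,
      # and the US-receiving F cells; unresponsive F cells keep baseline
      if (role == "F" && !roster$us_target[i]) ph1$us <- FALSE
      applied_current(role, within_phase(ph1), 0)
    }, numeric(1))
    base * jitter[i]
  })
}

# re-anchor a single phase at t = 0 so applied_current() can be evaluated
within_phase <- function(ph) {
  data.frame(t_start = 0, t_end = ph$t_end - ph$t_start, cs = ph$cs, us = ph$us)
}

#' Simulate a network under a stimulus paradigm
#'
#' Integrates the coupled system with classical RK4 (noise frozen within each
#' step), applies STDP events at detected spikes, and records voltages
#' (default every 1 ms), spike times, LFP current components (1 kHz, boxcar
#' anti-aliased) and plastic conductances (every 1 ms). Reproducible
#' bit-for-bit for a fixed `(config, seed)`.
#'
#' @param x a [network_config()] or an assembled "bla_network".
#' @param paradigm preset name for [paradigm_phases()] or a phase table.
#' @param duration optional duration (ms) for presets with a free duration.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param g_init initial conductance(s) for the plastic synapses (scalar or
#'   one per plastic edge), e.g. the endpoint of a conditioning run when
#'   probing post-conditioning dynamics.
#' @param plasticity set `FALSE` to freeze the plastic conductances (probe
#'   runs).
#' @param v_dt,lfp_dt,g_dt recording periods (ms).
#' @return object of class "bla_sim".
#' @export
simulate_network <- function(x, paradigm = "conditioning", duration = NULL,
                             seed = NULL, g_init = NULL, plasticity = TRUE,
                             v_dt = 1, lfp_dt = 1, g_dt = 1) {
  net <- if (inherits(x, "bla_config")) assemble(x) else x
  if (!inherits(net, "bla_network")) stop("x must be a config or network")
  config <- net$config
  roster <- net$roster
  edges <- net$edges
  phases <- if (is.character(paradigm)) paradigm_phases(paradigm, duration)
            else .validate_phases(paradigm)
  t_end <- max(phases$t_end)
  dt <- config$dt
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-9) stop("duration must be a multiple of dt")

  if (!is.null(seed)) set.seed(seed)
  nc <- nrow(roster)
  v0 <- runif(nc, -70, -60)
  jit <- if (config$iapp_jitter > 0)
    runif(nc, 1 - config$iapp_jitter, 1 + config$iapp_jitter) else rep(1, nc)

  # cell parameter matrix
  dt_noise <- if (config$noise_scaling == "printed") dt else sqrt(dt)
  par <- t(vapply(seq_len(nc), function(i) {
    over <- config$cell_overrides[[roster$role[i]]]
    p <- do.call(cell_params, c(list(roster$type[i]), over))
    .param_vector(p, dt_noise)
  }, numeric(12)))

  # applied-current schedule
  iapp <- .roster_iapp(roster, phases, config, jit)
  if (is.null(dim(iapp))) iapp <- matrix(iapp, nrow = nrow(phases))
  sched <- cbind(phases$t_start, phases$t_end, iapp)

  # Poisson event streams (CS first, then US: independent draws)
  units <- list(numeric(0), numeric(0))
  if (config$include_stimulus) {
    lam <- config$stimulus$lambda
    for (p in which(phases$cs))
      units[[1]] <- c(units[[1]], poisson_train(lam, phases$t_start[p],
                                                phases$t_end[p]))
    for (p in which(phases$us))
      units[[2]] <- c(units[[2]], poisson_train(lam, phases$t_start[p],
                                                phases$t_end[p]))
  }

  # synapse arrays; virtual drive edges appended last
  type_code <- CELL_TYPES[roster$type]
  n_edge <- nrow(edges)
  pre_role <- roster$role[edges$pre_id]
  form_of <- function(role) {
    switch(role, VIP = 0L, PV = 1L, SOM = 2L, 3L)
  }
  syn_form <- vapply(pre_role, form_of, integer(1))
  syn_lfp <- ifelse(!edges$internal, 0L, ifelse(edges$kind == "AMPA", 1L, 2L))
  syn_rule <- rep(-1L, n_edge)
  plastic_rows <- which(edges$plastic)
  if (plasticity && length(plastic_rows) > 0) {
    is_fvip <- roster$role[edges$pre_id[plastic_rows]] == "F"
    syn_rule[plastic_rows] <- ifelse(is_fvip, 1L, 0L)
  }
  syn_g <- edges$g
  if (!is.null(g_init) && length(plastic_rows) > 0) {
    ecs_pl <- plastic_rows[roster$role[edges$pre_id[plastic_rows]] == "ECS"]
    syn_g[ecs_pl] <- rep_len(g_init, length(ecs_pl))
  }

  syn_pre <- edges$pre_id - 1L
  syn_post <- edges$post_id - 1L
  syn_E <- edges$e_rev
  syn_tau <- edges$tau_decay
  if (config$include_stimulus) {
    aux_ids <- match(c("AUX_CS", "AUX_US"), roster$label)
    syn_pre <- c(syn_pre, nc + 0L, nc + 1L)
    syn_post <- c(syn_post, aux_ids - 1L)
    syn_form <- c(syn_form, 3L, 3L)
    syn_g <- c(syn_g, rep(config$stimulus$g_drive, 2))
    syn_E <- c(syn_E, 0, 0)
    syn_tau <- c(syn_tau, 2, 2)
    syn_lfp <- c(syn_lfp, 0L, 0L)
    syn_rule <- c(syn_rule, -1L, -1L)
  }

  # per-synapse ceilings scale with the number of converging plastic inputs,
  # mirroring the conductance scaling in build_connectivity()
  rules <- rbind(unlist(config$stdp[c("a_plus", "a_minus", "tau_plus",
                                      "tau_minus", "g_max")]),
                 unlist(config$stdp_f_vip[c("a_plus", "a_minus", "tau_plus",
                                            "tau_minus", "g_max")]))
  if (!identical(config$scale_excitatory, "printed")) {
    rules[1, 5] <- rules[1, 5] / max(1, config$n_cs_ecs)
    rules[2, 5] <- rules[2, 5] / max(1, config$n_us_f)
  }

  res <- run_network_cpp(
    cell_type = as.integer(type_code), cell_params = par, v0 = v0,
    iapp_sched = sched,
    syn_pre = as.integer(syn_pre), syn_post = as.integer(syn_post),
    syn_form = as.integer(syn_form), syn_g = as.numeric(syn_g),
    syn_E = as.numeric(syn_E), syn_tau = as.numeric(syn_tau),
    syn_lfp = as.integer(syn_lfp), syn_rule = as.integer(syn_rule),
    rules = rules, unit_events = units,
    pulse_width = config$stimulus$pulse_ms,
    dt = dt, t_end = t_end,
    v_every = max(1L, round(v_dt / dt)),
    lfp_every = max(1L, round(lfp_dt / dt)),
    g_every = max(1L, round(g_dt / dt)),
    spike_thr = 0, refractory = 2, noise_on = config$noise)

  V <- res$V
  colnames(V) <- roster$label
  spikes <- res$spikes
  names(spikes) <- roster$label
  lfp <- as.data.frame(res$lfp)
  names(lfp) <- c("ampa", "gaba", "d", "h", "nap",
                  "ampa_abs", "gaba_abs", "d_abs", "h_abs", "nap_abs")
  lfp <- cbind(time = as.numeric(res$lfp_time), lfp)
  g <- NULL
  if (length(plastic_rows) > 0 && ncol(res$g) == length(plastic_rows)) {
    gmat <- res$g
    colnames(gmat) <- paste0(edges$pre[plastic_rows], "->",
                             edges$post[plastic_rows])
    g <- list(time = as.numeric(res$g_time), g = gmat,
              pre = edges$pre[plastic_rows], post = edges$post[plastic_rows],
              scaled = !identical(config$scale_excitatory, "printed"))
  }
  edges$g_final <- res$syn_g_final[seq_len(n_edge)]

  structure(list(
    time = as.numeric(res$time_v), V = V, spikes = spikes, lfp = lfp, g = g,
    edges = edges, roster = roster, phases = phases, config = config,
    seed = seed, dt = dt, duration = t_end, transient_ms = 2000),
    class = "bla_sim")
}

#' @export
print.bla_sim <- function(x, ...) {
  cat("<bla_sim> ", nrow(x$roster), " cells, ", nrow(x$edges), " synapses, ",
      x$duration / 1000, " s at dt = ", x$dt, " ms\n", sep = "")
  rates <- spike_rates(x)
  cat("rates (Hz): ", paste(names(rates), round(rates, 1), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Mean firing rates of a simulation
#'
#' @param sim a "bla_sim" result.
#' @param from,to window (ms); defaults to the whole run.
#' @return named vector of rates (Hz).
#' @export
spike_rates <- function(sim, from = 0, to = sim$duration) {
  vapply(sim$spikes, function(s) sum(s >= from & s <= to) / (to - from) * 1000,
         numeric(1))
}
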