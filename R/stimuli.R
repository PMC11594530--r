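# Conditioned (CS) and unconditioned (US) stimulus machinery: Poisson spike
# trains into auxiliary relay neurons, applied-current switching, and the
# phase schedules of the conditioning paradigms.

#' Homogeneous Poisson spike train
#'
#' @param rate event rate (events/s, >= 0).
#' @param t0,t1 interval bounds (ms), `t0 <= t1`.
#' @return ordered event times (ms) in `(t0, t1)`. Consumes the R random
#'   number stream, so trains are reproducible under `set.seed()` and
#'   successive calls give independent streams.
#' @export
poisson_train <- function(rate, t0, t1) {
  stopifnot(rate >= 0, t0 <= t1)
  if (rate == 0 || t0 == t1) return(numeric(0))
  rate_ms <- rate / 1000
  # draw in blocks until the window is covered
  out <- numeric(0)
  t <- t0
  repeat {
    n_chunk <- max(16L, ceiling(1.2 * rate_ms * (t1 - t)))
    gaps <- rexp(n_chunk, rate_ms)
    times <- t + cumsum(gaps)
    out <- c(out, times[times < t1])
    if (times[n_chunk] >= t1) break
    t <- times[n_chunk]
  }
  out
}

#' Phase schedule of a conditioning paradigm
#'
#' Shipped presets:
#' * `"baseline"`: no CS, no US (pre-conditioning probe condition);
#' * `"paired_2s"`: 2 s of CS with US switched on after the first second;
#' * `"conditioning"`: CS and US effects on continuously (default 40 s,
#'   the one-trial fear-acquisition interval);
#' * `"conditioning15_30"`: 15 s of CS+US effects followed by 30 s of CS
#'   alone;
#' * `"cs_only"`: CS alone (post-conditioning probe).
#'
#' @param name preset name.
#' @param duration total duration (ms) for presets with a free duration.
#' @return data.frame with columns `t_start`, `t_end` (ms), `cs`, `us`
#'   (logical); non-overlapping ordered phases.
#' @export
paradigm_phases <- function(name = c("conditioning", "baseline", "paired_2s",
                                     "conditioning15_30", "cs_only"),
                            duration = NULL) {
  name <- match.arg(name)
  ph <- switch(name,
    baseline = data.frame(t_start = 0, t_end = duration %||% 10000,
                          cs = FALSE, us = FALSE),
    paired_2s = data.frame(t_start = c(0, 1000), t_end = c(1000, 2000),
                       cs = TRUE, us = c(FALSE, TRUE)),
    conditioning = data.frame(t_start = 0, t_end = duration %||% 40000,
                              cs = TRUE, us = TRUE),
    conditioning15_30 = data.frame(t_start = c(0, 15000),
                                   t_end = c(15000, 45000),
                                   cs = TRUE, us = c(TRUE, FALSE)),
    cs_only = data.frame(t_start = 0, t_end = duration %||% 10000,
                         cs = TRUE, us = FALSE))
  attr(ph, "paradigm") <- name
  ph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_phases <- function(phases) {
  stopifnot(all(phases$t_start < phases$t_end))
  if (nrow(phases) > 1 &&
      any(phases$t_start[-1] < phases$t_end[-nrow(phases)] - 1e-9))
    stop("phases must be non-overlapping and ordered")
  phases
}

#' Applied current for a cell role at a given time
#'
#' Baseline background drive per role, with the US-phase overrides: VIP
#' 4 uA/cm^2 at baseline and 5 during US; F 0.35 at baseline and 0.5 during
#' US; ECS 0.45, SOM 0.1 and PV 0 throughout; auxiliary relay cells receive
#' no background drive.
#'
#' @param role one of "VIP", "SOM", "PV", "ECS", "F", "AUX".
#' @param phases phase table from [paradigm_phases()].
#' @param t time (ms); must fall inside the schedule.
#' @return Iapp (uA/cm^2).
#' @export
applied_current <- function(role, phases, t) {
  .validate_phases(phases)
  i <- which(t >= phases$t_start & t < phases$t_end)
  if (length(i) == 0) {
    if (isTRUE(all.equal(t, phases$t_end[nrow(phases)]))) i <- nrow(phases)
    else stop("t = ", t, " ms lies outside the stimulus schedule")
  }
  us <- phases$us[i[1]]
  switch(role,
         VIP = if (us) 5 else 4,
         SOM = 0.1,
         PV = 0,
         ECS = 0.45,
         F = if (us) 0.5 else 0.35,
         AUX = 0,
         stop("unknown role: ", role))
}

#' Stimulus configuration
#'
#' @param lambda Poisson rate of the CS and US event trains (events/s).
#' @param g_e maximal AMPA conductance from the auxiliary relay neurons onto
#'   their targets (mS/cm^2).
#' @param g_drive AMPA conductance of the virtual Poisson unit onto the
#'   auxiliary relay cell (mS/cm^2); the default was calibrated once so
#'   that isolated ECS/PV driven through the relay fire at ~50 Hz.
#' @param pulse_ms duration (ms) for which the virtual unit's voltage sits at
#'   0 mV after each Poisson event.
#' @param routing `"standard"` routes the CS relay to ECS and PV and the US
#'   relay to F; `"us_to_pv"` lets PV receive the US relay drive instead of
#'   the CS relay.
#' @export
stimulus_config <- function(lambda = 800, g_e = 0.2, g_drive = 0.03,
                            pulse_ms = 1,
                            routing = c("standard", "us_to_pv")) {
  stopifnot(lambda >= 0, g_e >= 0, g_drive >= 0)
  list(lambda = lambda, g_e = g_e, g_drive = g_drive, pulse_ms = pulse_ms,
       routing = match.arg(routing))
}

#' Auxiliary relay wiring for the stimuli
#'
#' One auxiliary excitatory relay neuron per stimulus (CS, US), each driven
#' by its own Poisson event stream through a virtual AMPA unit. The CS relay
#' projects to the CS-receiving ECS cells and (in standard routing) to all PV
#' cells; the US relay projects to the US-receiving F cells, plus the PV
#' cells in the `us_to_pv` variant.
#'
#' @param config a [network_config()].
#' @return data.frame of AMPA drive edges (`pre` relay label, `post` label,
#'   ids, `g`, `e_rev`, `tau_decay`).
#' @export
build_stimulus_network <- function(config) {
  roster <- network_roster(config)
  stim <- config$stimulus
  aux <- roster[roster$role == "AUX", ]
  cs_aux <- aux[aux$label == "AUX_CS", ]
  us_aux <- aux[aux$label == "AUX_US", ]
  kin <- synapse_kinetics("E")
  tgt <- list()
  add <- function(pre_row, post_rows) {
    if (nrow(post_rows) == 0) return(NULL)
    data.frame(pre = pre_row$label, post = post_rows$label,
               pre_id = pre_row$id, post_id = post_rows$id,
               kind = "AMPA", g = stim$g_e, e_rev = kin$e_rev,
               tau_decay = kin$tau_decay, plastic = FALSE, g_max = NA,
               stringsAsFactors = FALSE)
  }
  ecs_cs <- roster[roster$role == "ECS" & roster$cs_target, ]
  f_us <- roster[roster$role == "F" & roster$us_target, ]
  pv <- roster[roster$role == "PV", ]
  tgt[[1]] <- add(cs_aux, ecs_cs)
  if (stim$routing == "standard") tgt[[2]] <- add(cs_aux, pv)
  else tgt[[2]] <- add(us_aux, pv)
  tgt[[3]] <- add(us_aux, f_us)
  out <- do.call(rbind, tgt)
  rownames(out) <- NULL
  out
}
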