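# Experiment drivers: natural-frequency scans, conditioning runs,
# interneuron ablations, and the pre/post low-theta biomarker comparison.

.isolated_config <- function(role, ...) {
  pops <- c(VIP = 0, SOM = 0, PV = 0, ECS = 0, F = 0)
  pops[[if (role %in% c("ECS", "F")) role else role]] <- 1
  network_config(populations = pops, include_synapses = FALSE,
                 include_stimulus = FALSE, ...)
}

#' Burst statistics of a spike train
#'
#' Bursts are segmented at inter-spike intervals exceeding `isi_gap`
#' (default 50 ms, between the model's ~25 ms intra-burst and ~300 ms
#' inter-burst intervals); the
#' intra-burst frequency is the inverse mean within-burst interval.
#'
#' @param spikes spike times (ms).
#' @param isi_gap burst-segmentation threshold (ms).
#' @return list with `n_bursts`, `burst_rate` (bursts/s), `intra_burst_hz`
#'   and `spikes_per_burst`.
#' @export
burst_statistics <- function(spikes, isi_gap = 50) {
  if (length(spikes) < 2)
    return(list(n_bursts = length(spikes), burst_rate = NA_real_,
                intra_burst_hz = NA_real_, spikes_per_burst = NA_real_))
  isi <- diff(spikes)
  burst_id <- cumsum(c(1, isi > isi_gap))
  within <- isi[isi <= isi_gap]
  n_bursts <- max(burst_id)
  span <- (spikes[length(spikes)] - spikes[1]) / 1000
  list(n_bursts = n_bursts,
       burst_rate = n_bursts / span,
       intra_burst_hz = if (length(within) > 0) 1000 / mean(within) else NA_real_,
       spikes_per_burst = length(spikes) / n_bursts)
}

#' Natural frequency of an isolated cell at baseline
#'
#' Simulates a single cell of the given role with its baseline applied
#' current and noise, no synapses attached. For VIP cells the scan also
#' reports gamma-burst structure (intra-burst frequency; spectral peak of
#' the burst rhythm below 6 Hz from the binned spike-count spectrum).
#'
#' @param role "VIP", "SOM", "PV", "ECS" or "F".
#' @param duration simulation length (ms); 30 s recommended for the VIP
#'   burst-rhythm spectral peak.
#' @param n_seeds number of realizations.
#' @param seed base seed; realization i uses `seed + i - 1`.
#' @param iapp optional applied-current override (uA/cm^2).
#' @return data.frame, one row per realization, with `rate_hz` and (VIP)
#'   `intra_burst_hz`, `burst_peak_hz`.
#' @export
natural_frequency_scan <- function(role, duration = 10000, n_seeds = 1,
                                   seed = 1, iapp = NULL) {
  over <- if (!is.null(iapp)) structure(list(iapp), names = role) else NULL
  config <- .isolated_config(role, iapp_override = over)
  out <- lapply(seq_len(n_seeds), function(i) {
    sim <- simulate_network(config, paradigm = "baseline",
                            duration = duration, seed = seed + i - 1)
    spk <- sim$spikes[[1]]
    spk <- spk[spk > sim$transient_ms]
    span <- (duration - sim$transient_ms) / 1000
    row <- data.frame(seed = seed + i - 1, rate_hz = length(spk) / span)
    if (role == "VIP") {
      bs <- burst_statistics(spk)
      row$intra_burst_hz <- bs$intra_burst_hz
      row$burst_rate_hz <- bs$burst_rate
      srs <- spike_rate_signal(list(spk), bin = 5,
                               t_range = c(sim$transient_ms, duration))
      psd <- multitaper_psd(srs, fmin = 0.1, fmax = 70)
      row$burst_peak_hz <- psd_peak(psd, 0.5, 6)
    }
    row
  })
  do.call(rbind, out)
}

.mk_seeds <- function(seed, n) seed + seq_len(n) - 1

#' Run a fear-conditioning experiment across realizations
#'
#' Each realization draws independent initial conditions, noise and stimulus
#' streams from its own seed. Returns per-realization plastic-conductance
#' trajectories, learner classification and (optionally) matched pre/post
#' spectral probes: a baseline run before conditioning, and afterwards
#' either the trained window of the conditioning run itself or a CS-only
#' run seeded with the learned conductances (see `post_probe`).
#'
#' @param paradigm `"conditioning"` (default 40 s) or `"conditioning15_30"`.
#' @param network `"single"` or `"heterogeneous"`.
#' @param n_realizations number of network realizations.
#' @param seed base seed.
#' @param duration optional conditioning duration override (ms).
#' @param config optional pre-built [network_config()] (overrides `network`).
#' @param probes also run the pre/post spectral probes.
#' @param probe_duration probe/window length (ms), transient included.
#' @param post_probe post-conditioning spectral source: `"conditioning"`
#'   (default) analyses the final window of the conditioning run itself —
#'   the trained network with CS and US effects present, the state in which
#'   the newly potentiated pathway drives the fear cells; `"cs_only"` runs a
#'   separate CS-alone probe seeded with the learned conductances.
#' @return list of class "bla_experiment": `g_time`, `g` (time x
#'   realizations, ECS->F pathway conductance), `learners` (data.frame),
#'   `seeds`, and when probed `pre`/`post` simulation lists.
#' @export
run_conditioning <- function(paradigm = "conditioning", network = "single",
                             n_realizations = 1, seed = 1, duration = NULL,
                             config = NULL, probes = FALSE,
                             probe_duration = 12000,
                             post_probe = c("conditioning", "cs_only")) {
  post_probe <- match.arg(post_probe)
  if (is.null(config))
    config <- network_config(heterogeneous = identical(network, "heterogeneous"))
  seeds <- .mk_seeds(seed, n_realizations)
  g_curves <- NULL
  res <- vector("list", n_realizations)
  for (i in seq_len(n_realizations)) {
    sim <- simulate_network(config, paradigm = paradigm, duration = duration,
                            seed = seeds[i])
    cls <- classify_learner(sim, paradigm = if (identical(paradigm,
      "conditioning15_30")) "conditioning15_30" else "conditioning")
    cls$seed <- seeds[i]
    gbar <- if (isTRUE(sim$g$scaled))
      rowSums(sim$g$g) / max(1, length(unique(sim$g$post)))
    else rowMeans(sim$g$g)
    if (is.null(g_curves)) {
      g_time <- sim$g$time
      g_curves <- matrix(NA_real_, length(gbar), n_realizations)
    }
    g_curves[, i] <- gbar
    pl_ecs <- sim$edges$plastic & grepl("^ECS", sim$edges$pre)
    entry <- list(classification = cls, g_final = sim$edges$g_final[pl_ecs])
    if (probes) {
      entry$pre <- simulate_network(config, paradigm = "baseline",
                                    duration = probe_duration,
                                    seed = seeds[i] + 100000L)
      entry$post <- if (post_probe == "conditioning") {
        .trained_window(sim, probe_duration)
      } else {
        simulate_network(config, paradigm = "cs_only",
                         duration = probe_duration,
                         seed = seeds[i] + 200000L, g_init = entry$g_final)
      }
    }
    res[[i]] <- entry
  }
  learners <- do.call(rbind, lapply(res, `[[`, "classification"))
  structure(list(
    paradigm = paradigm, config = config, seeds = seeds,
    g_time = g_time, g = g_curves,
    g_mean = rowMeans(g_curves), g_sd = apply(g_curves, 1, sd),
    learners = learners,
    n_learners = sum(learners$learner),
    pre = if (probes) lapply(res, `[[`, "pre"),
    post = if (probes) lapply(res, `[[`, "post"),
    g_final = lapply(res, `[[`, "g_final")),
    class = "bla_experiment")
}

#' Interneuron-ablation experiment
#'
#' Re-runs the conditioning experiment with one or two interneuron classes
#' removed (together with all their synapses).
#'
#' @param variant one of "full", "noVIP", "noSOM", "noPV", "noSOMPV".
#' @inheritParams run_conditioning
#' @export
run_ablation <- function(variant = c("full", "noVIP", "noSOM", "noPV",
                                     "noSOMPV"),
                         paradigm = "conditioning", network = "single",
                         n_realizations = 1, seed = 1, duration = NULL) {
  variant <- match.arg(variant)
  ablate <- switch(variant, full = character(), noVIP = "VIP", noSOM = "SOM",
                   noPV = "PV", noSOMPV = c("SOM", "PV"))
  config <- network_config(heterogeneous = identical(network, "heterogeneous"),
                           ablate = ablate)
  out <- run_conditioning(paradigm = paradigm, n_realizations = n_realizations,
                          seed = seed, duration = duration, config = config)
  out$variant <- variant
  out
}

# view of a conditioning run restricted to its final window: the "trained"
# state, with everything before the window flagged transient so the spectral
# pipeline analyses only the late, potentiated dynamics
.trained_window <- function(sim, window_ms) {
  out <- sim
  out$transient_ms <- max(sim$transient_ms, sim$duration - window_ms + 2000)
  out
}

.probe_band_powers <- function(sims, f_lo, f_hi, measure = "peak",
                               components = c("ampa", "gaba", "d", "h", "nap")) {
  vapply(sims, function(sim) {
    sig <- lfp_proxy(sim, components = components, discard_transient = TRUE)
    psd <- multitaper_psd(sig)
    if (measure == "integral") band_power(psd, f_lo, f_hi)
    else max(psd$power[psd$freq >= f_lo & psd$freq <= f_hi])
  }, numeric(1))
}

#' Pre/post spectral biomarker comparison
#'
#' Computes low-theta (2.5-4 Hz) and high-theta (12-14 Hz) LFP band powers
#' for matched pre- and post-conditioning probe runs, rank-sum p-values for
#' the pre/post contrast, and the post/pre power ratios of the AMPA-only and
#' GABA-only LFP components. The headline measure is the power density at
#' the band's spectral peak ("the peak of the low theta power"); the
#' band-integrated power is reported alongside under `integral`.
#'
#' @param pre,post matched lists of probe "bla_sim" runs.
#' @param bands named list of frequency bands (Hz).
#' @param measure `"peak"` (power density at the in-band spectral peak) or
#'   `"integral"` (trapezoidal band power) for the headline tables.
#' @return list with per-realization band-power tables (both measures),
#'   rank-sum tests and component power ratios.
#' @export
biomarker_analysis <- function(pre, post,
                               bands = list(low_theta = c(2.5, 4),
                                            high_theta = c(12, 14)),
                               measure = c("peak", "integral")) {
  if (length(pre) != length(post)) stop("pre and post groups must be matched")
  measure <- match.arg(measure)
  out <- list()
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    p_pre <- .probe_band_powers(pre, lo, hi, measure)
    p_post <- .probe_band_powers(post, lo, hi, measure)
    i_pre <- .probe_band_powers(pre, lo, hi, "integral")
    i_post <- .probe_band_powers(post, lo, hi, "integral")
    out[[b]] <- list(
      pre = p_pre, post = p_post,
      test = ranksum_compare(p_pre, p_post),
      median_ratio = stats::median(p_post) / stats::median(p_pre),
      integral = list(pre = i_pre, post = i_post,
                      test = ranksum_compare(i_pre, i_post)))
  }
  lo <- bands[[1]][1]; hi <- bands[[1]][2]
  comp_ratio <- function(components) {
    mean(.probe_band_powers(post, lo, hi, measure, components) /
         .probe_band_powers(pre, lo, hi, measure, components))
  }
  out$component_ratio <- c(ampa = comp_ratio("ampa"),
                           gaba = comp_ratio("gaba"))
  out
}

#' Full biomarker experiment: learners vs non-learners
#'
#' Learner branch: repeated 40 s heterogeneous conditioning runs, keeping
#' realizations that pass the learner criterion (pathway conductance above
#' 0.12 mS/cm^2), each matched with a baseline pre probe. Non-learner
#' branch: repeated 10 s conditioning runs, keeping realizations whose
#' ECS->F pathway conductance stays below 0.037 mS/cm^2. Post-conditioning
#' spectra come from the trained dynamics themselves (or from CS-only
#' probes, see `post_probe`).
#'
#' @param n_learner,n_nonlearner group sizes.
#' @param seed base seed.
#' @param config network configuration (heterogeneous by default).
#' @param probe_duration probe/window length (ms), transient included.
#' @param max_tries cap on harvesting attempts per group.
#' @inheritParams run_conditioning
#' @return list with the two [biomarker_analysis()] results plus the raw
#'   band-power tables and learner bookkeeping.
#' @export
biomarker_experiment <- function(n_learner = 5, n_nonlearner = 5, seed = 1,
                                 config = network_config(heterogeneous = TRUE),
                                 probe_duration = 12000, max_tries = 60,
                                 post_probe = c("conditioning", "cs_only")) {
  post_probe <- match.arg(post_probe)
  path_g <- function(sim) {
    pl <- sim$edges$plastic & grepl("^ECS", sim$edges$pre)
    if (identical(config$scale_excitatory, "printed"))
      mean(sim$edges$g_final[pl])
    else sum(sim$edges$g_final[pl]) /
      max(1, length(unique(sim$edges$post[pl])))
  }
  probe_pair <- function(sim, s) {
    pre <- simulate_network(config, paradigm = "baseline",
                            duration = probe_duration, seed = s + 100000L)
    post <- if (post_probe == "conditioning") .trained_window(sim, probe_duration)
            else simulate_network(config, paradigm = "cs_only",
                                  duration = probe_duration,
                                  seed = s + 200000L,
                                  g_init = sim$edges$g_final[sim$edges$plastic &
                                             grepl("^ECS", sim$edges$pre)])
    list(pre = pre, post = post)
  }
  # learners: full 40 s conditioning runs that pass the learner criterion
  l_pre <- list(); l_post <- list(); l_seeds <- integer(0); l_tries <- 0
  s <- seed
  while (length(l_pre) < n_learner && l_tries < max_tries) {
    l_tries <- l_tries + 1
    s <- s + 1L
    sim <- simulate_network(config, paradigm = "conditioning", seed = s)
    if (path_g(sim) > 0.12) {
      l_seeds <- c(l_seeds, s)
      pp <- probe_pair(sim, s)
      l_pre[[length(l_pre) + 1]] <- pp$pre
      l_post[[length(l_post) + 1]] <- pp$post
    }
  }
  # non-learners: short (10 s) conditioning runs whose pathway conductance
  # stays below the 15 s prediction threshold
  nl_pre <- list(); nl_post <- list(); nl_seeds <- integer(0); nl_tries <- 0
  s <- seed + 5000L
  while (length(nl_pre) < n_nonlearner && nl_tries < max_tries) {
    nl_tries <- nl_tries + 1
    s <- s + 1L
    sim <- simulate_network(config, paradigm = "conditioning",
                            duration = 10000, seed = s)
    if (path_g(sim) < 0.037) {
      nl_seeds <- c(nl_seeds, s)
      pp <- probe_pair(sim, s)
      nl_pre[[length(nl_pre) + 1]] <- pp$pre
      nl_post[[length(nl_post) + 1]] <- pp$post
    }
  }
  list(
    learner = if (length(l_pre) > 0) biomarker_analysis(l_pre, l_post),
    nonlearner = if (length(nl_pre) > 0) biomarker_analysis(nl_pre, nl_post),
    n_learner_found = length(l_pre), n_nonlearner_found = length(nl_pre),
    harvest_tries = c(learner = l_tries, nonlearner = nl_tries),
    learner_seeds = l_seeds, nonlearner_seeds = nl_seeds,
    post_probe = post_probe)
}
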