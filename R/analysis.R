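# LFP proxy, Thomson multitaper spectra, band power, learner classification
# and nonparametric pre/post comparisons.

#' LFP proxy of a simulation
#'
#' The LFP stands in for an extracellular field in a model without spatial
#' extension: the linear sum of the AMPA, GABA, D-, NaP- and H-currents of
#' the network's internal projections and interneurons (mode `"linear"`), or
#' the sum of their absolute values (mode `"rectified"`). Stimulus relay
#' drive is not part of the proxy. Components can be restricted to study
#' their separate contributions.
#'
#' @param sim a "bla_sim" result.
#' @param mode `"linear"` or `"rectified"`.
#' @param components subset of `c("ampa", "gaba", "d", "h", "nap")`.
#' @param discard_transient drop the initial transient flagged in the result
#'   (first 2000 ms) before returning.
#' @return list with `time` (ms), `x` (uA/cm^2) and `fs` (Hz).
#' @export
lfp_proxy <- function(sim, mode = c("linear", "rectified"),
                      components = c("ampa", "gaba", "d", "h", "nap"),
                      discard_transient = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "bla_sim"))
  bad <- setdiff(components, c("ampa", "gaba", "d", "h", "nap"))
  if (length(bad) > 0) stop("unknown LFP component(s): ", paste(bad, collapse = ", "))
  cols <- if (mode == "linear") components else paste0(components, "_abs")
  missing <- setdiff(cols, names(sim$lfp))
  if (length(missing) > 0) stop("missing current trace(s): ",
                                paste(missing, collapse = ", "))
  x <- rowSums(sim$lfp[, cols, drop = FALSE])
  time <- sim$lfp$time
  if (discard_transient) {
    keep <- time > sim$transient_ms
    x <- x[keep]
    time <- time[keep]
  }
  fs <- 1000 / diff(time[1:2])
  list(time = time, x = x, fs = fs)
}

#' Thomson multitaper power spectral density
#'
#' Multitaper PSD with discrete prolate spheroidal (Slepian) tapers and
#' Thomson's adaptive eigenspectrum weighting, reported one-sided on
#' 0.1-70 Hz by default.
#'
#' @param x signal (or a list with elements `x` and `fs` as produced by
#'   [lfp_proxy()] / [spike_rate_signal()]).
#' @param fs sampling rate (Hz); ignored when `x` carries its own.
#' @param nw time-half-bandwidth product (default 4).
#' @param k number of tapers (default `2 nw - 1`).
#' @param fmin,fmax reported frequency range (Hz).
#' @param demean subtract the mean before tapering.
#' @return data.frame of class "bla_psd" with `freq` (Hz) and `power`
#'   (signal^2/Hz).
#' @export
multitaper_psd <- function(x, fs = NULL, nw = 4, k = 2 * nw - 1,
                           fmin = 0.1, fmax = 70, demean = TRUE) {
  if (is.list(x)) {
    fs <- x$fs
    x <- x$x
  }
  if (is.null(fs)) stop("fs is required")
  n <- length(x)
  if (n < 2 * fs) stop("signal too short: need at least 2 s of samples")
  if (demean) x <- x - mean(x)
  tapers <- dpss_cpp(n, nw, k)
  nfft <- 2^ceiling(log2(n))
  eigvals <- .dpss_concentrations(tapers, nw, n)
  # eigenspectra
  half <- nfft %/% 2 + 1
  S_k <- matrix(0, half, k)
  for (j in seq_len(k)) {
    pad <- c(x * tapers[, j], rep(0, nfft - n))
    Y <- fft(pad)[seq_len(half)]
    S_k[, j] <- Mod(Y)^2
  }
  # Thomson adaptive weights
  sig2 <- sum(x^2) / n
  S <- rowMeans(S_k[, 1:min(2, k), drop = FALSE])
  if (sig2 == 0) S[] <- 0 else for (it in 1:20) {
    d <- S / (outer(S, eigvals) + outer(rep(sig2, half), 1 - eigvals))
    w <- d^2 * matrix(eigvals, half, k, byrow = TRUE)
    S_new <- rowSums(w * S_k) / rowSums(w)
    if (max(abs(S_new - S)) < 1e-12 * max(S_new, 1e-300)) { S <- S_new; break }
    S <- S_new
  }
  # one-sided density
  scale <- rep(2, half)
  scale[1] <- 1
  if (nfft %% 2 == 0) scale[half] <- 1
  psd <- S * scale / fs
  freq <- (seq_len(half) - 1) * fs / nfft
  keep <- freq >= fmin & freq <= fmax
  out <- data.frame(freq = freq[keep], power = psd[keep])
  class(out) <- c("bla_psd", "data.frame")
  attr(out, "nw") <- nw
  attr(out, "k") <- k
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  out
}

# concentration of each taper within the design band [-W, W], via the
# taper's spectrum (used for the adaptive weights)
.dpss_concentrations <- function(tapers, nw, n) {
  nfft <- 2^ceiling(log2(8 * n))
  W <- nw / n
  apply(tapers, 2, function(h) {
    H <- Mod(fft(c(h, rep(0, nfft - n))))^2
    f <- (seq_len(nfft) - 1) / nfft
    inband <- f <= W | f >= 1 - W
    min(1 - 1e-12, sum(H[inband]) / sum(H))
  })
}

#' Band power of a spectrum
#'
#' Trapezoidal integral of the power density over `[f_lo, f_hi]`, with the
#' band edges linearly interpolated so that adjacent bands partition their
#' union exactly.
#'
#' @param psd a "bla_psd" (or any data.frame with `freq` and `power`).
#' @param f_lo,f_hi band edges (Hz) within the spectrum's grid.
#' @return integrated power (signal^2).
#' @export
band_power <- function(psd, f_lo, f_hi) {
  if (f_hi <= f_lo) stop("empty band")
  f <- psd$freq
  p <- psd$power
  if (f_lo < f[1] - 1e-9 || f_hi > f[length(f)] + 1e-9)
    stop("band outside the spectrum's frequency grid")
  lo_p <- approx(f, p, f_lo, rule = 2)$y
  hi_p <- approx(f, p, f_hi, rule = 2)$y
  inside <- f > f_lo & f < f_hi
  fg <- c(f_lo, f[inside], f_hi)
  pg <- c(lo_p, p[inside], hi_p)
  sum(diff(fg) * (head(pg, -1) + tail(pg, -1)) / 2)
}

#' Peak frequency of a spectrum
#'
#' @param psd a "bla_psd".
#' @param f_lo,f_hi search window (Hz).
#' @return frequency (Hz) of the maximum power density in the window.
#' @export
psd_peak <- function(psd, f_lo = -Inf, f_hi = Inf) {
  sel <- psd$freq >= f_lo & psd$freq <= f_hi
  psd$freq[sel][which.max(psd$power[sel])]
}

#' Population spike-rate signal
#'
#' Binned population spike counts (all cells pooled), mean-subtracted, ready
#' for [multitaper_psd()].
#'
#' @param spikes list of per-cell spike-time vectors (ms), or a "bla_sim".
#' @param bin bin width (ms).
#' @param t_range window (ms); defaults to the full span.
#' @return list with `time` (bin centres, ms), `x` and `fs` (Hz).
#' @export
spike_rate_signal <- function(spikes, bin = 5, t_range = NULL) {
  stopifnot(bin > 0)
  if (inherits(spikes, "bla_sim")) {
    if (is.null(t_range)) t_range <- c(0, spikes$duration)
    spikes <- spikes$spikes
  }
  all_t <- unlist(spikes, use.names = FALSE)
  if (is.null(t_range))
    t_range <- c(0, if (length(all_t) > 0) max(all_t) + bin else bin)
  edges <- seq(t_range[1], t_range[2], by = bin)
  if (length(edges) < 3) stop("window too short for the bin width")
  counts <- if (length(all_t) == 0) rep(0, length(edges) - 1)
            else hist(all_t[all_t >= t_range[1] & all_t < edges[length(edges)]],
                      breaks = edges, plot = FALSE)$counts
  list(time = edges[-length(edges)] + bin / 2, x = counts - mean(counts),
       fs = 1000 / bin, total = sum(counts))
}

#' Classify a realization as learner or non-learner
#'
#' In the 40 s one-trial paradigm a realization is a learner when the ECS->F
#' conductance exceeds 0.12 mS/cm^2 at 40 s. In the 15 s + 30 s paradigm,
#' realizations whose conductance exceeds 0.037 mS/cm^2 at the end of the
#' 15 s US-effect interval are predicted to complete learning during the
#' CS-only tail. For multi-synapse (heterogeneous) networks the summed
#' pathway conductance converging on one fear cell (averaged over F cells)
#' is used; it reduces to the single synapse's conductance in the
#' single-cell network.
#'
#' @param sim a "bla_sim" with a plastic ECS->F pathway, or a list with
#'   `time`/`g` as in `sim$g`.
#' @param paradigm `"conditioning"` (threshold 0.12 at 40 s / run end) or
#'   `"conditioning15_30"` (threshold 0.037 at 15 s).
#' @param thresholds named thresholds, overridable for sensitivity checks.
#' @return data.frame with `g_15s`, `g_end`, `learner`, `threshold`.
#' @export
classify_learner <- function(sim, paradigm = c("conditioning",
                                               "conditioning15_30"),
                             thresholds = c(end = 0.12, mid = 0.037)) {
  paradigm <- match.arg(paradigm)
  g <- if (inherits(sim, "bla_sim")) sim$g else sim
  if (is.null(g)) stop("no plastic conductance trajectory recorded")
  # equivalent single-synapse conductance of the ECS->F pathway: the
  # per-synapse mean under printed (unscaled) conductances, or the summed
  # input per F cell when the per-synapse values are divided by the
  # converging count; both equal the single synapse's g in the single-cell
  # network
  gbar <- if (isTRUE(g$scaled)) rowSums(g$g) / max(1, length(unique(g$post)))
          else rowMeans(g$g)
  t <- g$time
  g_at <- function(tt) {
    if (tt > t[length(t)] + 1e-9) stop("trajectory shorter than the paradigm")
    gbar[which.min(abs(t - tt))]
  }
  g_end <- gbar[length(gbar)]
  g_15 <- if (t[length(t)] >= 15000) g_at(15000) else NA_real_
  if (paradigm == "conditioning") {
    thr <- thresholds[["end"]]
    learner <- g_end > thr
  } else {
    if (is.na(g_15)) stop("trajectory shorter than the paradigm")
    thr <- thresholds[["mid"]]
    learner <- g_15 > thr
  }
  data.frame(g_15s = g_15, g_end = g_end, learner = learner, threshold = thr)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact null distribution for small samples without ties, normal
#' approximation (with continuity and tie correction) otherwise.
#'
#' @param group_a,group_b numeric samples.
#' @return list with `statistic` (rank-sum W of the first group) and
#'   `p_value`.
#' @export
ranksum_compare <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) <= 25 && length(group_b) <= 25
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
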