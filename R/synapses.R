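# GABAa and AMPA synaptic kinetics and the fear-circuit connectivity graph.

# open-rate form codes shared with the C++ engine
OPEN_FORMS <- c(VIP = 0L, PV = 1L, SOM = 2L, E = 3L)

# presynaptic-type-specific kinetics
SYN_KINETICS <- data.frame(
  pre_type = c("VIP", "PV", "SOM", "E"),
  kind     = c("GABAa", "GABAa", "GABAa", "AMPA"),
  e_rev    = c(-80, -80, -80, 0),
  tau_decay = c(10, 8.3, 20, 2),
  stringsAsFactors = FALSE
)

#' Open-rate function of a synaptic receptor
#'
#' Voltage-dependent rate at which the receptor gate opens, specific to the
#' presynaptic cell type: `2(1 + tanh(V/4))` for VIP, `7.5(1 + tanh(V/0.1))`
#' for PV, `2.5(1 + tanh(V/0.1))` for SOM (all GABAa) and `5(1 + tanh(V/4))`
#' for AMPA from excitatory cells.
#'
#' @param pre_type presynaptic cell type ("VIP", "PV", "SOM", "E").
#' @param v_pre presynaptic membrane potential (mV); vectorised.
#' @return opening rate (1/ms), nonnegative and bounded.
#' @export
presynaptic_open_rate <- function(pre_type, v_pre) {
  if (!pre_type %in% names(OPEN_FORMS))
    stop("pre_type must be one of ", paste(names(OPEN_FORMS), collapse = ", "))
  vapply(v_pre, function(v) open_rate_cpp(OPEN_FORMS[[pre_type]], v),
         numeric(1))
}

#' Synaptic kinetics constants for a presynaptic type
#'
#' @inheritParams presynaptic_open_rate
#' @return list with `kind`, `e_rev` (mV) and `tau_decay` (ms).
#' @export
synapse_kinetics <- function(pre_type) {
  row <- SYN_KINETICS[SYN_KINETICS$pre_type == pre_type, ]
  if (nrow(row) != 1) stop("unknown presynaptic type: ", pre_type)
  list(kind = row$kind, e_rev = row$e_rev, tau_decay = row$tau_decay)
}

#' Time derivative of a synaptic gate
#'
#' `ds/dt = rate(V_pre) (1 - s) - s / tau_decay`; the gate stays in \[0, 1\]
#' under integration.
#'
#' @param pre_type presynaptic cell type.
#' @param s gating value in \[0, 1\].
#' @param v_pre presynaptic membrane potential (mV).
#' @param tau_decay decay constant (ms); defaults to the type-specific value.
#' @return ds/dt (1/ms).
#' @export
synapse_gate_derivative <- function(pre_type, s, v_pre,
                                    tau_decay = synapse_kinetics(pre_type)$tau_decay) {
  stopifnot(all(s >= 0 & s <= 1))
  presynaptic_open_rate(pre_type, v_pre) * (1 - s) - s / tau_decay
}

#' Synaptic current onto a postsynaptic cell
#'
#' `g s (V_post - E_rev)` in the outward-positive convention; the membrane
#' equation subtracts this term, so a GABAa synapse (`E_rev = -80` mV)
#' hyperpolarises a cell held above its reversal.
#'
#' @param g maximal conductance (mS/cm^2).
#' @param s gating value in \[0, 1\].
#' @param v_post postsynaptic membrane potential (mV).
#' @param e_rev reversal potential (mV).
#' @return current (uA/cm^2).
#' @export
synaptic_current <- function(g, s, v_post, e_rev) {
  stopifnot(all(g >= 0), all(s >= 0 & s <= 1))
  g * s * (v_post - e_rev)
}

# The nine internal projections. Inhibitory conductances are divided by the
# presynaptic population size as printed (note the printed VIP->SOM scaling
# uses the postsynaptic count; see network_config(scale_by=)). Excitatory
# conductances are divided by the number of stimulus-receiving presynaptic
# cells so that the total drive each target receives matches the single-cell
# circuit (in which these counts are 1 and the printed values apply
# unchanged); the plastic ECS->F ceiling scales the same way, and learner
# classification uses the summed pathway conductance per F cell.
.projection_table <- function(config) {
  n <- config$populations
  scale_exc <- !identical(config$scale_excitatory, "printed")
  n_cs <- if (scale_exc) max(1, config$n_cs_ecs) else 1
  n_us <- if (scale_exc) max(1, config$n_us_f) else 1
  vip_som_div <- if (config$scale_by == "printed") n[["SOM"]] else n[["VIP"]]
  data.frame(
    from = c("VIP", "VIP", "PV", "PV", "SOM", "SOM", "ECS", "F", "F"),
    to   = c("PV", "SOM", "F", "ECS", "F", "ECS", "F", "PV", "VIP"),
    g    = c(1 / n[["VIP"]], 1 / vip_som_div, 0.5 / n[["PV"]], 0.4 / n[["PV"]],
             0.4 / n[["SOM"]], 0.4 / n[["SOM"]], 0, 0.5 / n_us, 0.01 / n_us),
    plastic = c(rep(FALSE, 6), TRUE, FALSE, config$plastic_f_vip),
    g_max = c(rep(NA, 6), config$stdp$g_max / n_cs, NA,
              if (config$plastic_f_vip) config$stdp_f_vip$g_max / n_us else NA),
    stringsAsFactors = FALSE
  )
}

#' Build the fear-circuit connectivity graph
#'
#' All-to-all edges for the nine projection types (six inhibitory:
#' VIP->PV, VIP->SOM, PV->F, PV->ECS, SOM->F, SOM->ECS; three excitatory:
#' ECS->F, F->PV, F->VIP), with per-synapse inhibitory conductances scaled by
#' population size and the ECS->F pathway starting at zero conductance and
#' flagged plastic. In heterogeneous networks the plastic edges run from every
#' CS-receiving ECS cell to every US-receiving F cell. Ablated populations
#' contribute no cells and no edges.
#'
#' @param config a [network_config()].
#' @return data.frame edge list: `pre`, `post` (cell labels), `pre_id`,
#'   `post_id`, `kind`, `g` (mS/cm^2), `e_rev` (mV), `tau_decay` (ms),
#'   `plastic`, `g_max`.
#' @export
build_connectivity <- function(config) {
  roster <- network_roster(config)
  n <- config$populations
  if (any(n < 0)) stop("population sizes must be nonnegative")
  proj <- .projection_table(config)
  edges <- list()
  for (i in seq_len(nrow(proj))) {
    pr <- proj[i, ]
    pre_cells <- roster[roster$role == pr$from, ]
    post_cells <- roster[roster$role == pr$to, ]
    if (pr$from == "ECS") pre_cells <- pre_cells[pre_cells$cs_target, ]
    if (pr$plastic && pr$to == "F") post_cells <- post_cells[post_cells$us_target, ]
    if (nrow(pre_cells) == 0 || nrow(post_cells) == 0) next
    kin <- synapse_kinetics(ifelse(pr$from %in% c("ECS", "F"), "E", pr$from))
    grid <- expand.grid(p = seq_len(nrow(pre_cells)),
                        q = seq_len(nrow(post_cells)))
    edges[[length(edges) + 1L]] <- data.frame(
      pre = pre_cells$label[grid$p], post = post_cells$label[grid$q],
      pre_id = pre_cells$id[grid$p], post_id = post_cells$id[grid$q],
      kind = kin$kind, g = pr$g, e_rev = kin$e_rev, tau_decay = kin$tau_decay,
      plastic = pr$plastic, g_max = pr$g_max, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
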