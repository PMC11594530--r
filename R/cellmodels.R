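# Hodgkin-Huxley cell types: VIP, SOM and PV interneurons and excitatory
# projection neurons (E; used for ECS, F and the auxiliary relay cells).

CELL_TYPES <- c(VIP = 0L, SOM = 1L, PV = 2L, E = 3L)

# gating variables integrated for each cell type; m is instantaneous
# (algebraic m_inf) for VIP and E
GATES <- list(
  VIP = c("h", "n", "a", "b"),
  SOM = c("m", "h", "n", "hf", "hs", "p"),
  PV  = c("m", "h", "n"),
  E   = c("h", "n")
)

# intrinsic currents per type
CHANNELS <- list(
  VIP = c("Na", "K", "L", "D"),
  SOM = c("Na", "K", "L", "H", "P"),
  PV  = c("Na", "K", "L"),
  E   = c("Na", "K", "L")
)

.check_cell_type <- function(cell_type) {
  if (!is.character(cell_type) || length(cell_type) != 1L ||
      !cell_type %in% names(CELL_TYPES)) {
    stop("cell_type must be one of ", paste(names(CELL_TYPES), collapse = ", "),
         call. = FALSE)
  }
  cell_type
}

#' Load the versioned cell-parameter table
#'
#' Maximal conductances (mS/cm^2), reversal potentials (mV), baseline applied
#' current (uA/cm^2), noise scale and membrane capacitance (uF/cm^2) for the
#' four cell types. The table ships with the package as delimited text; a
#' loader validates that every cell type carries exactly the conductances its
#' channel set requires (D only for VIP; H and NaP only for SOM).
#'
#' @param path path to a parameter table; defaults to the shipped table.
#' @return data.frame with one row per cell type.
#' @export
load_cell_params <- function(path = system.file("extdata", "cell_params.csv",
                                                package = "blafear")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_type", "g_na", "e_na", "g_k", "e_k", "g_l", "e_l",
              "g_d", "g_h", "e_h", "g_p", "iapp_baseline", "noise_k", "cm")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("parameter table lacks columns: ", paste(missing, collapse = ", "))
  if (!setequal(tab$cell_type, names(CELL_TYPES)))
    stop("parameter table must contain exactly the cell types ",
         paste(names(CELL_TYPES), collapse = ", "))
  cond <- c("g_na", "g_k", "g_l", "g_d", "g_h", "g_p")
  if (any(tab[, cond] < 0, na.rm = TRUE)) stop("negative maximal conductance")
  if (any(tab$cm <= 0)) stop("cm must be positive")
  for (ct in tab$cell_type) {
    row <- tab[tab$cell_type == ct, ]
    if (ct != "VIP" && isTRUE(row$g_d > 0))
      stop("D-current conductance is VIP-specific")
    if (ct != "SOM" && (isTRUE(row$g_h > 0) || isTRUE(row$g_p > 0)))
      stop("H/NaP conductances are SOM-specific")
    if (ct == "VIP" && !isTRUE(row$g_d > 0)) stop("VIP requires g_d")
    if (ct == "SOM" && !(isTRUE(row$g_h > 0) && isTRUE(row$g_p > 0)))
      stop("SOM requires g_h and g_p")
  }
  tab
}

.param_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_cell_params()
    cache
  }
})

#' Cell parameters for one cell type
#'
#' @param cell_type one of "VIP", "SOM", "PV", "E".
#' @param ... named overrides of individual fields (e.g. `g_d = 0` to block
#'   the D-current, or `g_na = 0, g_k = 0` for a passive leak-only membrane).
#' @return named list of parameters for the cell type.
#' @export
cell_params <- function(cell_type, ...) {
  .check_cell_type(cell_type)
  row <- .param_table()
  row <- as.list(row[row$cell_type == cell_type, ])
  over <- list(...)
  bad <- setdiff(names(over), names(row))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  row[names(over)] <- over
  row
}

# 12-column numeric parameter vector consumed by the C++ engine
.param_vector <- function(p, dt) {
  num <- function(x) if (is.null(x) || is.na(x)) 0 else as.numeric(x)
  c(num(p$g_na), num(p$e_na), num(p$g_k), num(p$e_k), num(p$g_l), num(p$e_l),
    num(p$g_d), num(p$g_h), num(p$e_h), num(p$g_p),
    num(p$noise_k) * dt, num(p$cm))
}

#' Gating steady state and time constant
#'
#' Evaluates `x_inf(V)` and `tau_x(V)` for one gating variable of one cell
#' type. Channels formulated with opening/closing rates (SOM, PV, E) are
#' converted through `x_inf = alpha/(alpha+beta)`, `tau = 1/(alpha+beta)`,
#' with removable singularities guarded by a series expansion. For the
#' instantaneous sodium activation of VIP and E cells (`channel = "m"`) the
#' steady state is returned with `tau = NA` because the gate is algebraic and
#' never integrated.
#'
#' @param cell_type one of "VIP", "SOM", "PV", "E".
#' @param channel gating variable name valid for the cell type.
#' @param v membrane potential (mV).
#' @return list with elements `x_inf` (in \[0, 1\]) and `tau` (ms).
#' @export
steady_state_and_tau <- function(cell_type, channel, v) {
  .check_cell_type(cell_type)
  stopifnot(is.finite(v))
  gates <- GATES[[cell_type]]
  if (channel == "m" && cell_type %in% c("VIP", "E")) {
    return(list(x_inf = minf_inst_cpp(CELL_TYPES[[cell_type]], v), tau = NA_real_))
  }
  if (!channel %in% gates)
    stop("channel '", channel, "' is not defined for ", cell_type, " cells")
  kin <- gate_kinetics_cpp(CELL_TYPES[[cell_type]], v)
  i <- match(channel, gates)
  list(x_inf = kin[i, 1], tau = kin[i, 2])
}

#' Steady-state gating vector at a holding potential
#'
#' @inheritParams steady_state_and_tau
#' @return named numeric vector over the cell type's integrated gates.
#' @export
gating_steady_state <- function(cell_type, v) {
  .check_cell_type(cell_type)
  gates <- GATES[[cell_type]]
  kin <- gate_kinetics_cpp(CELL_TYPES[[cell_type]], v)
  out <- kin[seq_along(gates), 1]
  names(out) <- gates
  out
}

.check_gating <- function(cell_type, gating) {
  gates <- GATES[[cell_type]]
  if (!all(gates %in% names(gating)))
    stop("gating must contain ", paste(gates, collapse = ", "), " for ",
         cell_type)
  g <- as.numeric(gating[gates])
  if (any(g < 0 | g > 1)) stop("gating values must lie in [0, 1]")
  g
}

#' Intrinsic membrane currents
#'
#' Hodgkin-Huxley currents (outward-positive, uA/cm^2) for one cell:
#' Na, K and leak for every type, plus the D-current for VIP
#' (`g_d a^3 b (V - E_K)`) and the H- and persistent-sodium currents for SOM
#' (`g_h (0.65 hf + 0.35 hs)(V - E_H)`, `g_p p (V - E_Na)`). VIP and E cells
#' use the instantaneous `m_inf^3 h` sodium activation; SOM and PV integrate
#' `m` as a state variable. The VIP fast potassium current carries two
#' activation gates (`n^2`); all other types carry four (`n^4`).
#'
#' @param cell_type one of "VIP", "SOM", "PV", "E".
#' @param v membrane potential (mV).
#' @param gating named vector of gating values for the cell type.
#' @param params parameter list from [cell_params()].
#' @return named numeric vector of currents (uA/cm^2).
#' @export
membrane_currents <- function(cell_type, v, gating, params = cell_params(cell_type)) {
  .check_cell_type(cell_type)
  g <- .check_gating(cell_type, gating)
  pad <- c(g, rep(0, 6 - length(g)))
  cur <- membrane_currents_cpp(CELL_TYPES[[cell_type]], v, pad,
                               .param_vector(params, dt = 0.05))
  names(cur) <- CHANNELS[[cell_type]]
  cur
}

#' Time derivatives of the gating variables
#'
#' First-order relaxation `dx/dt = (x_inf(V) - x)/tau_x(V)` for every
#' integrated gate of the cell type; exactly zero at the voltage-dependent
#' fixed point.
#'
#' @inheritParams membrane_currents
#' @return named numeric vector of derivatives (1/ms).
#' @export
gating_derivatives <- function(cell_type, v, gating) {
  .check_cell_type(cell_type)
  g <- .check_gating(cell_type, gating)
  gates <- GATES[[cell_type]]
  kin <- gate_kinetics_cpp(CELL_TYPES[[cell_type]], v)
  d <- (kin[seq_along(gates), 1] - g) / kin[seq_along(gates), 2]
  names(d) <- gates
  d
}
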