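## Single-unit response functions for the network's internal nodes and the
## alternative architectures. All responses are built from two primitives:
## Gaussian tuning exp(-(x - u)^2 / 2 sigma^2) and the semi-linear gain
## f(x) = max(x, 0), applied to task quantities scaled by psi(t) or phi(t).

# node kind -> does the node carry a modulation onset v?
.node_kinds <- c(
  eye             = TRUE,   # TE-tuned Gaussian, gain-modulated by HE
  hand_dyn        = FALSE,  # Gaussian over the scaled displacement psi(t)*TH
  eye_hand        = TRUE,   # TE-tuned Gaussian, gain-modulated by psi(t)*TH
  hand_static     = FALSE,  # Gaussian over the static displacement TH
  eye_hand_rising = TRUE,   # Gaussian over phi(t)*TH, gain-modulated by HE
  te_gauss        = FALSE,  # Gaussian over TE (no gain)
  te_rising       = FALSE,  # Gaussian over phi(t)*TE
  he_gauss        = FALSE,  # Gaussian over HE
  he_falling      = FALSE,  # Gaussian over psi(t)*HE
  te_he_mixed     = TRUE    # Gaussian over phi(t)*TE, gain over psi(t)*HE
)

# main-network nodes have defined pre-target responses (target terms -> 1)
.pretarget_nodes <- c("eye", "hand_dyn", "eye_hand")

node_uses_modulation <- function(node) {
  unknown <- setdiff(unique(node), names(.node_kinds))
  if (length(unknown)) {
    stop("unknown node kind: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(.node_kinds[node])
}

#' Semi-linear gain modulation function
#'
#' `f(x) = x` for `x >= 0` and 0 otherwise; the rectifier used for all
#' modulatory (gain-field) factors in the network.
#'
#' @param x numeric vector.
#' @return numeric vector, `pmax(x, 0)`.
#' @export
semilinear_gain <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  pmax(x, 0)
}

#' Construct a table of model units
#'
#' A unit is described by its node kind, its primary tuning onset `u`, an
#' optional modulation onset `v` (only for node kinds with a multiplicative
#' gain factor), the sign of its gain slope, the amplitude `A` and the common
#' length-scale `sigma` of tuning and modulation.
#'
#' @param node character vector of node kinds; one of `"eye"`, `"hand_dyn"`,
#'   `"eye_hand"`, `"hand_static"`, `"eye_hand_rising"`, `"te_gauss"`,
#'   `"te_rising"`, `"he_gauss"`, `"he_falling"`, `"te_he_mixed"`.
#' @param u numeric, primary tuning onsets (degrees).
#' @param v numeric, modulation onsets (degrees); `NA` for single-onset nodes.
#' @param gain_sign `+1` or `-1`, slope sign of the semi-linear gain.
#' @param A positive amplitude (rate units).
#' @param sigma positive tuning/modulation length-scale (degrees).
#' @param unit_id optional character ids; generated if missing.
#' @return a `data.frame` with one row per unit.
#' @export
unit_spec <- function(node, u, v = NA_real_, gain_sign = 1L, A = 30,
                      sigma = 15, unit_id = NULL) {
  n <- max(length(node), length(u), length(v), length(gain_sign))
  node <- rep_len(node, n)
  uses_v <- node_uses_modulation(node)
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  gain_sign <- rep_len(as.integer(gain_sign), n)
  A <- rep_len(as.numeric(A), n)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(A <= 0) || any(sigma <= 0)) {
    stop("`A` and `sigma` must be positive", call. = FALSE)
  }
  if (!all(gain_sign %in% c(-1L, 1L))) {
    stop("`gain_sign` must be +1 or -1", call. = FALSE)
  }
  if (any(uses_v & is.na(v))) {
    stop("modulated node kinds require a modulation onset `v`", call. = FALSE)
  }
  v[!uses_v] <- NA_real_
  if (is.null(unit_id)) {
    unit_id <- sprintf("%s_%03d", node, seq_len(n))
  }
  data.frame(unit_id = unit_id, node = node, u = u, v = v,
             gain_sign = gain_sign, A = A, sigma = sigma,
             stringsAsFactors = FALSE)
}

# n_units x n_conditions Gaussian tuning matrix; x per condition, u per unit
.gauss <- function(x, u, sigma) {
  d <- outer(-u, x, "+")          # x[j] - u[i]
  exp(-d^2 / (2 * sigma^2))
}

# n_units x n_conditions rectified gain matrix f(gain_sign * (x - v) / sigma)
.fgain <- function(x, v, gain_sign, sigma) {
  d <- outer(-v, x, "+") * gain_sign / sigma   # recycles down columns
  pmax(d, 0)
}

#' Noiseless unit responses for a set of conditions at one time point
#'
#' Evaluates the node response equations at a single normalized task time.
#' For `t` in the pre-target epoch (`t < -1`) the target-related factors of
#' the main-network nodes are set to unity: the eye node reduces to its gain
#' factor alone and the two displacement-dependent nodes to the constant
#' amplitude `A`. The alternative-network node kinds have no stated
#' pre-target response and raise an error there.
#'
#' @param units a unit table from [unit_spec()] or [build_population()].
#' @param cond a condition table from [task_conditions()].
#' @param t scalar normalized task time in `[-2, 1]`.
#' @return a numeric matrix, units x conditions, of non-negative rates.
#' @export
unit_response <- function(units, cond, t) {
  stopifnot(is.data.frame(units), is.data.frame(cond), length(t) == 1L)
  node_uses_modulation(units$node)  # validates kinds
  pretarget <- t < -1
  ps <- psi(t)
  ph <- 1 - ps
  out <- matrix(NA_real_, nrow(units), nrow(cond),
                dimnames = list(units$unit_id, NULL))
  for (kind in unique(units$node)) {
    i <- which(units$node == kind)
    uu <- units$u[i]; vv <- units$v[i]
    gs <- units$gain_sign[i]; A <- units$A[i]; sg <- units$sigma[i]
    if (length(unique(sg)) != 1L) {
      stop("units within a node must share `sigma`", call. = FALSE)
    }
    sg <- sg[1]
    if (pretarget) {
      if (!kind %in% .pretarget_nodes) {
        stop("node kind '", kind, "' has no defined pre-target response",
             call. = FALSE)
      }
      m <- switch(kind,
        eye      = A * .fgain(cond$HE, vv, gs, sg),
        hand_dyn = matrix(A, length(i), nrow(cond)),
        eye_hand = matrix(A, length(i), nrow(cond)))
    } else {
      m <- switch(kind,
        eye             = A * .gauss(cond$TE, uu, sg) *
                              .fgain(cond$HE, vv, gs, sg),
        hand_dyn        = A * .gauss(ps * cond$TH, uu, sg),
        eye_hand        = A * .gauss(cond$TE, uu, sg) *
                              .fgain(ps * cond$TH, vv, gs, sg),
        hand_static     = A * .gauss(cond$TH, uu, sg),
        eye_hand_rising = A * .gauss(ph * cond$TH, uu, sg) *
                              .fgain(cond$HE, vv, gs, sg),
        te_gauss        = A * .gauss(cond$TE, uu, sg),
        te_rising       = A * .gauss(ph * cond$TE, uu, sg),
        he_gauss        = A * .gauss(cond$HE, uu, sg),
        he_falling      = A * .gauss(ps * cond$HE, uu, sg),
        te_he_mixed     = A * .gauss(ph * cond$TE, uu, sg) *
                              .fgain(ps * cond$HE, vv, gs, sg))
    }
    out[i, ] <- m
  }
  out
}

#' Add Gaussian observation noise to a rate table
#'
#' Perturbs every entry by an independent draw from `N(0, sd)`. Draws come
#' from R's current random stream, so reproducibility is controlled by
#' `set.seed()` in the caller (the experiment runners seed one stream per
#' experiment and consume it in a fixed order). Noisy rates are deliberately
#' not clipped at zero: clipping would distort the additive-noise assumption
#' of the downstream regressions.
#'
#' @param rates numeric matrix or vector of rates.
#' @param sd non-negative noise standard deviation (rate units).
#' @return object of the same shape with noise added.
#' @export
add_noise <- function(rates, sd = 5) {
  stopifnot(is.numeric(rates), length(sd) == 1L, sd >= 0)
  if (sd == 0) return(rates)
  rates + stats::rnorm(length(rates), mean = 0, sd = sd)
}
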