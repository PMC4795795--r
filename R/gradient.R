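## Gradient (resultant-vector) analysis of condition-response matrices.
##
## For each unit and each pair of analysis parameters (T and H, T and E,
## H and E; the third parameter held at 0 degrees), responses on a 5 x 5
## position grid are differentiated by finite differences. Because a
## relative spatial variable is indistinguishable from its inverse, every
## element gradient has its angle doubled (magnitude preserved) before the
## vector sum, so that gradients along equivalent axes reinforce instead of
## cancelling. Unit resultants are summed into node resultants; hybrid
## populations combine per-node mean resultants with composition weights.

.pair_defs <- list(
  "T-H" = list(p1 = "T", p2 = "H", fixed = "E"),
  "T-E" = list(p1 = "T", p2 = "E", fixed = "H"),
  "H-E" = list(p1 = "H", p2 = "E", fixed = "T")
)

.pair_conditions <- function(pair, positions, fixed_value = 0) {
  def <- .pair_defs[[pair]]
  if (is.null(def)) {
    stop("invalid parameter pair: ", pair, call. = FALSE)
  }
  grid <- expand.grid(p1 = positions, p2 = positions, KEEP.OUT.ATTRS = FALSE)
  vals <- list(E = NULL, H = NULL, T = NULL)
  vals[[def$p1]] <- grid$p1
  vals[[def$p2]] <- grid$p2
  vals[[def$fixed]] <- fixed_value
  task_conditions(vals$E, vals$H, vals$T)
}

#' 5 x 5 activity matrix for one unit
#'
#' Noiseless responses of a single unit over the position grid of a
#' parameter pair, the remaining parameter held constant. The first
#' parameter of the pair varies along rows, in ascending order.
#'
#' @param unit a one-row unit table.
#' @param pair `"T-H"`, `"T-E"` or `"H-E"`.
#' @param t normalized task time.
#' @param positions grid positions (degrees), default `seq(-20, 20, 10)`.
#' @param fixed_value value of the held-constant parameter.
#' @return a 5 x 5 matrix (rows = first parameter).
#' @export
activity_matrix <- function(unit, pair, t, positions = seq(-20, 20, by = 10),
                            fixed_value = 0) {
  stopifnot(nrow(unit) == 1L)
  cond <- .pair_conditions(pair, positions, fixed_value)
  r <- unit_response(unit, cond, t)
  matrix(r[1, ], nrow = length(positions))  # p1 varies fastest -> rows
}

# finite differences of an n_units x k x k response array along both grid
# axes: central in the interior, one-sided at the edges; h is the grid step.
.grad_components <- function(arr, h) {
  k <- dim(arr)[2]
  d1 <- array(0, dim(arr))
  d2 <- array(0, dim(arr))
  d1[, 2:(k - 1), ] <- (arr[, 3:k, , drop = FALSE] -
                          arr[, 1:(k - 2), , drop = FALSE]) / (2 * h)
  d1[, 1, ] <- (arr[, 2, ] - arr[, 1, ]) / h
  d1[, k, ] <- (arr[, k, ] - arr[, k - 1, ]) / h
  d2[, , 2:(k - 1)] <- (arr[, , 3:k, drop = FALSE] -
                          arr[, , 1:(k - 2), drop = FALSE]) / (2 * h)
  d2[, , 1] <- (arr[, , 2] - arr[, , 1]) / h
  d2[, , k] <- (arr[, , k] - arr[, , k - 1]) / h
  list(d1 = d1, d2 = d2)
}

# per-unit doubled-angle resultants from an n x k x k array
.unit_resultants <- function(arr, h) {
  g <- .grad_components(arr, h)
  mag <- sqrt(g$d1^2 + g$d2^2)
  theta <- atan2(g$d2, g$d1)
  cbind(x = rowSums(mag * cos(2 * theta), dims = 1),
        y = rowSums(mag * sin(2 * theta), dims = 1))
}

#' Doubled-angle gradient resultant of one activity matrix
#'
#' Element gradients by finite differences, each angle doubled with the
#' magnitude preserved, then summed. The first matrix axis (rows) is the x
#' component of the gradient space.
#'
#' @param m a square activity matrix.
#' @param h grid step in degrees between adjacent rows/columns.
#' @return numeric `c(x, y)` resultant in doubled-angle space.
#' @export
unit_gradient_resultant <- function(m, h = 10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(is.finite(m)))
  arr <- array(m, dim = c(1, dim(m)))
  drop(.unit_resultants(arr, h))
}

#' Population resultant, optionally a weighted hybrid
#'
#' Sums unit resultants within each node; a pure population returns the
#' plain sum. For hybrid populations the per-node mean resultants are
#' combined with composition weights (e.g. eye : hand : eye-and-hand =
#' 0.25 : 0.50 : 0.25), emulating a recorded population whose cells come
#' from the different representations in those proportions.
#'
#' @param unit_res units x 2 matrix of unit resultants.
#' @param nodes node kind per unit.
#' @param weights `NULL` for a plain sum, or a named vector of composition
#'   weights over node kinds summing to 1.
#' @return numeric `c(x, y)`.
#' @export
population_resultant <- function(unit_res, nodes, weights = NULL) {
  stopifnot(ncol(unit_res) == 2L, nrow(unit_res) == length(nodes))
  if (is.null(weights)) return(colSums(unit_res))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("hybrid weights must sum to 1", call. = FALSE)
  }
  out <- c(x = 0, y = 0)
  for (nd in names(weights)) {
    i <- which(nodes == nd)
    if (length(i) == 0) next
    out <- out + weights[[nd]] * colMeans(unit_res[i, , drop = FALSE])
  }
  out
}

#' Gradient resultants across the whole task
#'
#' Iterates the gradient analysis over every parameter pair and time step,
#' on noiseless responses (set `noise_sd` for robustness checks). Emits,
#' per (pair, t), the population resultant in doubled-angle space, its
#' magnitude, and the halved angle used to read directions against the
#' parameter axes.
#'
#' @param units unit table (screened population).
#' @param time_points normalized task times, default the 0.1-step grid over
#'   the three epochs.
#' @param pairs parameter pairs to analyze.
#' @param positions grid positions per parameter.
#' @param weights optional hybrid composition weights (see
#'   [population_resultant()]).
#' @param noise_sd optional response noise SD (default 0, noiseless).
#' @return a `data.frame`: `pair`, `t`, `x`, `y`, `magnitude`,
#'   `angle_deg` (doubled space), `halved_angle_deg` in `(-90, 90]`.
#' @export
gradient_series <- function(units, time_points = seq(-2, 1, by = 0.1),
                            pairs = names(.pair_defs),
                            positions = seq(-20, 20, by = 10),
                            weights = NULL, noise_sd = 0) {
  h <- diff(positions)[1]
  k <- length(positions)
  rows <- list()
  cond_by_pair <- lapply(pairs, .pair_conditions, positions = positions)
  names(cond_by_pair) <- pairs
  for (t in time_points) {
    for (pair in pairs) {
      r <- unit_response(units, cond_by_pair[[pair]], t)
      if (noise_sd > 0) r <- add_noise(r, noise_sd)
      arr <- array(r, dim = c(nrow(units), k, k))
      ures <- .unit_resultants(arr, h)
      res <- population_resultant(ures, units$node, weights)
      mag <- sqrt(sum(res^2))
      ang <- if (mag > 0) atan2(res[2], res[1]) * 180 / pi else 0
      half <- ang / 2
      if (half <= -90) half <- half + 180
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair, t = t, x = res[[1]], y = res[[2]], magnitude = mag,
        angle_deg = ang, halved_angle_deg = half, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Normalized epoch samples of a gradient series
#'
#' Extracts the resultants at the pre-target, go, and movement-offset
#' epochs (normalized times -1.5, 0 and 1) and scales each to unit length;
#' zero resultants stay zero.
#'
#' @param series output of [gradient_series()].
#' @param epochs named times of the sampled epochs.
#' @return a `data.frame` with `pair`, `epoch`, `t`, unit-length `x`, `y`,
#'   `magnitude` (pre-normalization), `halved_angle_deg`.
#' @export
epoch_samples <- function(series,
                          epochs = c(pre_target = -1.5, go = 0, offset = 1)) {
  rows <- list()
  for (e in seq_along(epochs)) {
    tt <- epochs[[e]]
    sel <- series[abs(series$t - tt) < 1e-9, , drop = FALSE]
    if (nrow(sel) == 0) {
      stop("epoch t = ", tt, " not covered by the series", call. = FALSE)
    }
    mag <- sel$magnitude
    sel$x <- ifelse(mag > 0, sel$x / mag, 0)
    sel$y <- ifelse(mag > 0, sel$y / mag, 0)
    sel$epoch <- names(epochs)[e]
    rows[[e]] <- sel[, c("pair", "epoch", "t", "x", "y", "magnitude",
                         "halved_angle_deg")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Axial (mod-180) angular distance in degrees
#'
#' Distance between two axes, in `[0, 90]`; halved-angle directions are
#' axes because the underlying gradients were angle-doubled.
#'
#' @param a,b angles in degrees.
#' @return numeric distance(s) in degrees.
#' @export
axial_distance <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}
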