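#' Default eye/hand position pairs for the delay task
#'
#' Five `(E, H)` pairs on the `sigma/2`-spaced position grid: the central
#' pair, the eye displaced alone by `sigma/2` to either side, and eye and
#' hand displaced to opposite sides by `sigma`. The set dissociates `TE`,
#' `HE` and `TH` in the reference-frame regression and spans hand-in-eye
#' positions out to `+/- 2*sigma`, so that the semi-linear gain of
#' modulated units is exercised through its clipping region and not only
#' on its linear part.
#'
#' @param sigma tuning length-scale in degrees.
#' @return a 5 x 2 data.frame with columns `E`, `H`.
#' @export
default_eh_pairs <- function(sigma = 15) {
  data.frame(E = c(0, sigma / 2, -sigma / 2, sigma, -sigma),
             H = c(0, 0, 0, -sigma, sigma))
}

#' Delay-period reference-frame task conditions
#'
#' Targets occupy 9 positions from `-2*sigma` to `+2*sigma`, spaced
#' `sigma/2` apart, crossed with 5 eye/hand position pairs: 45 conditions,
#' observed at the end of the delay period (`t = 0`). Condition order is
#' deterministic with targets varying fastest.
#'
#' @param sigma tuning length-scale in degrees.
#' @param eh_pairs data.frame of eye/hand pairs (columns `E`, `H`);
#'   defaults to [default_eh_pairs()].
#' @return a condition table (see [task_conditions()]) with attribute
#'   `t = 0`.
#' @export
delay_task_conditions <- function(sigma = 15, eh_pairs = default_eh_pairs(sigma)) {
  stopifnot(is.data.frame(eh_pairs), all(c("E", "H") %in% names(eh_pairs)))
  targets <- seq(-2 * sigma, 2 * sigma, by = sigma / 2)
  E <- rep(eh_pairs$E, each = length(targets))
  H <- rep(eh_pairs$H, each = length(targets))
  T <- rep(targets, times = nrow(eh_pairs))
  if (any(abs(c(E, H, T)) > 3 * sigma)) {
    stop("task positions must lie within +/- 3*sigma", call. = FALSE)
  }
  cond <- task_conditions(E, H, T)
  attr(cond, "t") <- 0
  attr(cond, "label") <- "delay"
  cond
}

#' Center-out screening task conditions
#'
#' Eye and hand at the central position (`E = H = 0`) with the target at the
#' 9 delay-task locations. Used to screen units for a discernible tuning
#' peak before reference-frame analysis.
#'
#' @inheritParams delay_task_conditions
#' @return a condition table of 9 rows; attribute `task_range` holds the
#'   target range used by the peak-location criterion.
#' @export
screening_task_conditions <- function(sigma = 15) {
  targets <- seq(-2 * sigma, 2 * sigma, by = sigma / 2)
  cond <- task_conditions(E = 0, H = 0, T = targets)
  attr(cond, "t") <- 0
  attr(cond, "label") <- "screening"
  attr(cond, "task_range") <- range(targets)
  cond
}

#' Full-factorial gradient-task conditions
#'
#' All independent combinations of eye, hand and target positions over
#' `-20` to `+20` degrees in steps of 10 (125 conditions), tracked across
#' the whole task: pre-target, delay and movement epochs sampled every 0.1
#' units of normalized time (31 time points from -2 to 1).
#'
#' @param positions positions per parameter, default `seq(-20, 20, 10)`.
#' @param t_step time step in normalized task time.
#' @return a condition table of `length(positions)^3` rows with attribute
#'   `time_points`.
#' @export
gradient_task_conditions <- function(positions = seq(-20, 20, by = 10),
                                     t_step = 0.1) {
  grid <- expand.grid(T = positions, H = positions, E = positions,
                      KEEP.OUT.ATTRS = FALSE)
  cond <- task_conditions(grid$E, grid$H, grid$T)
  attr(cond, "time_points") <- seq(-2, 1, by = t_step)
  attr(cond, "label") <- "gradient"
  cond
}
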