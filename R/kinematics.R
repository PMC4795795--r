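#' Temporal interpolation function psi(t)
#'
#' The decreasing unit interpolation function that scales the displacement
#' vector during a reach. Task time is dimensionless, with the three epochs
#' fixed at pre-target `[-2, -1)`, delay `[-1, 0]` and movement `(0, 1]`.
#' `psi` is 1 throughout the delay period (back-extrapolated to the pre-target
#' epoch) and decays linearly to 0 across the movement, so that the desired
#' hand position advances from the initial posture to the target.
#'
#' @param t numeric vector of normalized task times in `[-2, 1]`.
#' @return numeric vector of interpolation values in `[0, 1]`.
#' @seealso [phi()], [desired_trajectory()]
#' @examples
#' psi(c(-0.5, 0, 0.5, 1))
#' @export
psi <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  if (any(t < -2 | t > 1)) {
    stop("normalized task time must lie in [-2, 1]", call. = FALSE)
  }
  ifelse(t <= 0, 1, 1 - t)
}

#' Rising counterpart of psi(t)
#'
#' `phi(t) = 1 - psi(t)`: zero until movement onset, rising linearly to 1 at
#' movement offset. Used by the alternative network architectures.
#'
#' @inheritParams psi
#' @return numeric vector in `[0, 1]`.
#' @export
phi <- function(t) 1 - psi(t)

#' Task conditions for a 1D reach task
#'
#' Builds a condition table from eye (`E`), initial hand (`H`) and target
#' (`T`) positions, in degrees of eccentricity along a single axis. The
#' derived relative quantities are attached as columns: target in eye
#' coordinates `TE = T - E`, hand in eye coordinates `HE = H - E`, and the
#' displacement vector `TH = TE - HE = T - H`.
#'
#' @param E,H,T numeric vectors (recycled to a common length) of eye, hand
#'   and target positions in degrees.
#' @return a `data.frame` with columns `E`, `H`, `T`, `TE`, `HE`, `TH`.
#' @examples
#' task_conditions(E = 0, H = -10, T = 20)
#' @export
task_conditions <- function(E, H, T) {
  n <- max(length(E), length(H), length(T))
  E <- rep_len(as.numeric(E), n)
  H <- rep_len(as.numeric(H), n)
  T <- rep_len(as.numeric(T), n)
  if (any(!is.finite(c(E, H, T)))) {
    stop("all positions must be finite", call. = FALSE)
  }
  data.frame(E = E, H = H, T = T, TE = T - E, HE = H - E, TH = T - H)
}

#' Displacement vector of a task condition
#'
#' First stage of the two-stage trajectory computation: the displacement
#' vector `TH = TE - HE = T - H`, independent of eye position.
#'
#' @param cond a condition table from [task_conditions()].
#' @return numeric vector of displacements in degrees.
#' @export
displacement_vector <- function(cond) {
  stopifnot(is.data.frame(cond), all(c("T", "H") %in% names(cond)))
  cond$T - cond$H
}

#' Desired hand trajectory in eye-centered coordinates
#'
#' Second stage of the trajectory computation: `he(t) = TE - psi(t) * TH`.
#' During the delay period this reduces to the initial hand position in eye
#' coordinates (`HE`); at movement offset it equals the target in eye
#' coordinates (`TE`).
#'
#' @param cond a condition table from [task_conditions()].
#' @param t scalar normalized task time in `[-2, 1]`.
#' @return numeric vector, desired eye-centered hand position per condition.
#' @export
desired_trajectory <- function(cond, t) {
  stopifnot(is.data.frame(cond), all(c("TE", "TH") %in% names(cond)),
            length(t) == 1L)
  cond$TE - psi(t) * cond$TH
}

#' Phenomenological hand position during movement
#'
#' The descriptive model of actual reach kinematics,
#' `h(t) = T - psi(t) * (T - H)`, defined on the movement epoch only.
#' Consistency contract with the internal computation:
#' `h(t) - E == desired_trajectory(cond, t)` for all `t` in `[0, 1]`.
#'
#' @inheritParams desired_trajectory
#' @param t scalar movement time in `[0, 1]`.
#' @return numeric vector of extrinsic hand positions in degrees.
#' @export
hand_position <- function(cond, t) {
  stopifnot(is.data.frame(cond), all(c("T", "H") %in% names(cond)),
            length(t) == 1L)
  if (t < 0 || t > 1) {
    stop("`t` must lie in the movement epoch [0, 1]", call. = FALSE)
  }
  cond$T - psi(t) * (cond$T - cond$H)
}
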