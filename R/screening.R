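#' Bounds for the center-out tuning fit
#'
#' Amplitude 0-100, peak location -45 to 45 degrees, width 10-30 degrees,
#' baseline 0-10 rate units.
#' @return named list of `c(lower, upper)` pairs.
#' @export
tuning_fit_bounds <- function() {
  list(a = c(0, 100), mu = c(-45, 45), s = c(10, 30), c = c(0, 10))
}

.tuning_model <- function(p, targets) {
  p["a"] * exp(-(targets - p["mu"])^2 / (2 * p["s"]^2)) + p["c"]
}

# deterministic multistart grid for the 4-parameter tuning fit
.tuning_grid <- function(targets, s_starts = c(10, 15, 20, 25, 30)) {
  combos <- expand.grid(mu = targets, s = s_starts, KEEP.OUT.ATTRS = FALSE)
  X <- vapply(seq_len(nrow(combos)),
              function(k) exp(-(targets - combos$mu[k])^2 / (2 * combos$s[k]^2)),
              numeric(length(targets)))
  list(combos = combos, X = X)
}

#' Fit a four-parameter Gaussian tuning curve
#'
#' Fits `r = a * exp(-(T - mu)^2 / (2 s^2)) + c` to center-out responses by
#' bounded least squares, with a deterministic multistart over peak
#' locations (the targets) and widths `{10, 15, 20, 25, 30}`; ties are
#' broken toward the smallest width, then the smallest `|mu|`. The
#' spike-variance-explained statistic `sve = r2 * a` combines fit quality
#' and fitted modulation depth.
#'
#' @param responses numeric vector of rates, one per target.
#' @param targets numeric vector of target positions (degrees).
#' @return a one-row `data.frame`: `a`, `mu`, `s`, `c`, `r2`, `sve`,
#'   `degenerate`. Constant responses yield the degenerate fit (`a` at its
#'   lower bound, `r2 = 0`) rather than an error.
#' @export
fit_tuning_curve <- function(responses, targets) {
  stopifnot(length(responses) == length(targets), length(targets) >= 5)
  fits <- screen_fits(matrix(responses, nrow = 1), targets)
  fits[, c("a", "mu", "s", "c", "r2", "sve", "degenerate")]
}

# batch tuning fits: Y is n_units x n_targets
screen_fits <- function(Y, targets) {
  b <- tuning_fit_bounds()
  grid <- .tuning_grid(targets)
  prof <- profile_linear_fits(Y, grid$X, b$a, b$c)
  n <- nrow(Y)
  out <- data.frame(a = numeric(n), mu = numeric(n), s = numeric(n),
                    c = numeric(n), r2 = numeric(n), sve = numeric(n),
                    degenerate = logical(n))
  lower <- c(a = b$a[1], mu = b$mu[1], s = b$s[1], c = b$c[1])
  upper <- c(a = b$a[2], mu = b$mu[2], s = b$s[2], c = b$c[2])
  # tie-break order: rss, then smaller s, then smaller |mu|
  ord <- order(grid$combos$s, abs(grid$combos$mu))
  for (i in seq_len(n)) {
    y <- Y[i, ]
    if (stats::var(y) <= 1e-12 * max(1, mean(y)^2)) {
      out$a[i] <- b$a[1]; out$mu[i] <- 0; out$s[i] <- b$s[1]
      out$c[i] <- .clamp(mean(y), b$c[1], b$c[2])
      out$r2[i] <- 0; out$sve[i] <- 0; out$degenerate[i] <- TRUE
      next
    }
    rss_i <- prof$rss[i, ord]
    k <- ord[which.min(rss_i)]
    start <- c(a = unname(prof$a[i, k]), mu = grid$combos$mu[k],
               s = grid$combos$s[k], c = unname(prof$c[i, k]))
    fit <- fit_bounded_ls(y, function(p) .tuning_model(p, targets),
                          start, lower, upper)
    p <- fit$par
    rss <- min(fit$rss, prof$rss[i, k])
    if (fit$rss > prof$rss[i, k]) {  # polish should never lose to its start
      p <- start
    }
    out$a[i] <- p[["a"]]; out$mu[i] <- p[["mu"]]
    out$s[i] <- p[["s"]]; out$c[i] <- p[["c"]]
    out$r2[i] <- r_squared(y, rss)
    out$sve[i] <- out$r2[i] * out$a[i]
  }
  out
}

#' Peak-location and SVE acceptance rule
#'
#' A unit passes the screen when its fitted peak lies at least `s/2` inside
#' the task range and its spike variance explained reaches the threshold.
#'
#' @param fit a tuning fit (row) from [fit_tuning_curve()], or a data.frame
#'   of them.
#' @param task_range numeric `c(lo, hi)` target range of the screening task.
#' @param sve_threshold acceptance threshold on `sve` (default 10).
#' @return logical vector.
#' @export
screen_unit <- function(fit, task_range, sve_threshold = 10) {
  stopifnot(length(task_range) == 2L)
  if (task_range[1] >= task_range[2]) {
    stop("`task_range` must satisfy lo < hi", call. = FALSE)
  }
  in_range <- fit$mu >= task_range[1] + fit$s / 2 &
    fit$mu <= task_range[2] - fit$s / 2
  in_range & fit$sve >= sve_threshold & !fit$degenerate
}

#' Screen a population on center-out responses
#'
#' Fits every unit's center-out responses to the four-parameter Gaussian
#' and applies the peak-location and SVE criteria.
#'
#' @param units a unit table.
#' @param rates units x targets matrix of (possibly noisy) rates from the
#'   screening task.
#' @param targets screening-task target positions.
#' @param sve_threshold SVE acceptance threshold.
#' @return a screening report: `unit_id`, `node`, fit parameters, `r2`,
#'   `sve`, `accepted`.
#' @export
screen_population <- function(units, rates, targets, sve_threshold = 10) {
  stopifnot(nrow(units) == nrow(rates), ncol(rates) == length(targets))
  fits <- screen_fits(rates, targets)
  fits$unit_id <- units$unit_id
  fits$node <- units$node
  fits$accepted <- screen_unit(fits, range(targets), sve_threshold)
  fits[, c("unit_id", "node", "a", "mu", "s", "c", "r2", "sve",
           "degenerate", "accepted")]
}
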