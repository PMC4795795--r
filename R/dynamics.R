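#' Unweighted linear trend of a time series
#'
#' Ordinary least-squares line through `(t, value)` pairs with uniform
#' weighting; used to summarize the drift of class means and sizes.
#'
#' @param t,value numeric vectors of equal length (`>= 2` non-missing pairs).
#' @return named numeric vector `c(slope, intercept)`.
#' @export
linear_trend <- function(t, value) {
  ok <- is.finite(t) & is.finite(value)
  if (sum(ok) < 2) stop("need at least 2 points for a trend", call. = FALSE)
  co <- stats::coef(stats::lm(value[ok] ~ t[ok]))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Time-resolved reclassification during simulated movement
#'
#' Repeats the delay-period analysis chain at successive points of the
#' movement epoch: at each `t` the responses are re-simulated with the
#' interpolation `psi(t)` applied (fresh noise draws from the experiment's
#' stream), units are re-screened for task responsiveness, refitted and
#' reclassified. Class membership is re-evaluated at every time point, which
#' is what produces the characteristic drift of the residual hand-classified
#' subpopulation. Sizes are reported as fractions of each class's size at
#' the first time point (which must be `t = 0`, the delay-period state).
#'
#' @inheritParams delay_period_analysis
#' @param time_points normalized times in `[0, 1]`, starting at 0.
#' @return list: `trajectory` (rows `t` x class with `mean_w`, `n_units`,
#'   `size_fraction`; class `"all"` aggregates the classified units),
#'   `trends` (per-class linear trends of both series), `fits` (per-`t`
#'   classification tables).
#' @export
evolve_classification <- function(units, sigma = 15, noise_sd = 5,
                                  sve_threshold = 10, alpha = 0.01,
                                  eh_pairs = default_eh_pairs(sigma),
                                  time_points = c(0, 0.25, 0.5, 0.75, 1),
                                  seed = NULL) {
  stopifnot(all(time_points >= 0 & time_points <= 1),
            time_points[1] == 0, !is.unsorted(time_points))
  if (!is.null(seed)) set.seed(seed)
  classes <- c("eye", "hand", "intermediate", "indeterminate", "all")
  fits_by_t <- list()
  rows <- list()
  base_n <- NULL
  for (t in time_points) {
    res <- delay_period_analysis(units, sigma = sigma, noise_sd = noise_sd,
                                 sve_threshold = sve_threshold, alpha = alpha,
                                 eh_pairs = eh_pairs, t = t)
    fits <- res$fits
    fits_by_t[[sprintf("%.3f", t)]] <- fits
    n_by <- function(cl) {
      if (cl == "all") sum(fits$class != "indeterminate")
      else sum(fits$class == cl)
    }
    w_by <- function(cl) {
      keep <- if (cl == "all") fits$class != "indeterminate"
              else fits$class == cl
      if (!any(keep)) NA_real_ else mean(fits$w[keep])
    }
    n_t <- vapply(classes, n_by, numeric(1))
    if (is.null(base_n)) base_n <- n_t
    rows[[length(rows) + 1L]] <- data.frame(
      t = t, class = classes, mean_w = vapply(classes, w_by, numeric(1)),
      n_units = n_t,
      size_fraction = ifelse(base_n > 0, n_t / base_n,
                             ifelse(n_t > 0, Inf, NA_real_)),
      row.names = NULL)
  }
  trajectory <- do.call(rbind, rows)
  trends <- do.call(rbind, lapply(classes, function(cl) {
    d <- trajectory[trajectory$class == cl, ]
    tw <- if (sum(is.finite(d$mean_w)) >= 2) linear_trend(d$t, d$mean_w)
          else c(slope = NA_real_, intercept = NA_real_)
    ts <- if (sum(is.finite(d$size_fraction)) >= 2)
            linear_trend(d$t, d$size_fraction)
          else c(slope = NA_real_, intercept = NA_real_)
    data.frame(class = cl, w_slope = tw[["slope"]],
               w_intercept = tw[["intercept"]],
               size_slope = ts[["slope"]], size_intercept = ts[["intercept"]])
  }))
  list(trajectory = trajectory, trends = trends, fits = fits_by_t)
}
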