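#' Exhaustive grid-search fit of the reference-frame model
#'
#' A brute-force reference fitter: enumerates regular grids in the
#' nonlinear parameters `(w, mu, s, g)` over their full bounds and profiles
#' the amplitude and baseline in closed form (under their box constraints)
#' at every grid point. Deliberately independent of the bounded
#' Levenberg-Marquardt path in [fit_reference_frame()], so the two can be
#' cross-checked: on well-posed problems the polished fit should land
#' within one grid cell of the exhaustive optimum.
#'
#' @inheritParams fit_reference_frame
#' @param w_step,mu_step,s_step,g_step grid resolutions (defaults 0.01,
#'   0.5 deg, 0.5 deg, 0.005 per deg).
#' @return list with `par` (named vector `a, mu, s, g, c, w`) and `rss`.
#' @export
grid_search_reference_frame <- function(responses, cond, w_step = 0.01,
                                        mu_step = 0.5, s_step = 0.5,
                                        g_step = 0.005) {
  b <- ref_fit_bounds()
  stopifnot(length(responses) == nrow(cond))
  gr <- function(bounds, step) seq(bounds[1], bounds[2], by = step)
  out <- .grid_search_rf(as.numeric(responses),
                         cond$TE, cond$TH, cond$HE,
                         gr(b$w, w_step), gr(b$mu, mu_step),
                         gr(b$s, s_step), gr(b$g, g_step),
                         b$a, b$c)
  list(par = c(a = out$a, mu = out$mu, s = out$s, g = out$g,
               c = out$c, w = out$w),
       rss = out$rss)
}
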