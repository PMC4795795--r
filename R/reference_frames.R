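#' Bounds for the six-parameter reference-frame model
#'
#' Amplitude 1-100, peak -45 to 45 degrees, width 10-30 degrees, gain slope
#' -0.15 to 0.15 per degree, baseline 0-10, reference-frame weight -1.5 to
#' 2.5 (so that fits may land beyond the pure frames at `w = 0` and `w = 1`).
#' @return named list of `c(lower, upper)` pairs.
#' @export
ref_fit_bounds <- function() {
  list(a = c(1, 100), mu = c(-45, 45), s = c(10, 30),
       g = c(-0.15, 0.15), c = c(0, 10), w = c(-1.5, 2.5))
}

# model predictions; p carries w unless w_fixed is given
.ref_model <- function(p, cond, w_fixed = NULL) {
  w <- if (is.null(w_fixed)) p[["w"]] else w_fixed
  TX <- w * cond$TE + (1 - w) * cond$TH
  p[["a"]] * exp(-(TX - p[["mu"]])^2 / (2 * p[["s"]]^2)) *
    (1 + p[["g"]] * cond$HE) + p[["c"]]
}

#' Precompute the multistart basis for a condition set
#'
#' Gaussian basis columns over a deterministic grid of (w, mu, s) used to
#' seed the bounded fits; shared across units because the conditions are.
#'
#' @param cond delay-task condition table.
#' @param w_grid,mu_grid,s_grid start grids for the nonlinear parameters.
#' @return an opaque list consumed by [fit_reference_frame()].
#' @export
ref_start_grid <- function(cond,
                           w_grid = c(-1, 0, 0.25, 0.5, 0.75, 1, 2),
                           mu_grid = seq(-30, 30, by = 7.5),
                           s_grid = c(10, 15, 20, 25, 30)) {
  combos <- expand.grid(mu = mu_grid, s = s_grid, w = w_grid,
                        KEEP.OUT.ATTRS = FALSE)
  X <- vapply(seq_len(nrow(combos)), function(k) {
    TX <- combos$w[k] * cond$TE + (1 - combos$w[k]) * cond$TH
    exp(-(TX - combos$mu[k])^2 / (2 * combos$s[k]^2))
  }, numeric(nrow(cond)))
  list(combos = combos, X = X, n = nrow(cond))
}

#' Fit the reference-frame regression to one unit
#'
#' Bounded least-squares fit of
#' `r = a * exp(-(TX - mu)^2 / (2 s^2)) * (1 + g * HE) + c` with
#' `TX = w * TE + (1 - w) * TH`, where `w` interpolates between a pure
#' hand-centered (`w = 0`) and a pure eye-centered (`w = 1`) encoding of
#' the target. With `w_fixed` at 0 or 1 the corresponding five-parameter
#' pure-frame submodel is fitted instead.
#'
#' Starts come from profiling amplitude and baseline over a deterministic
#' (w, mu, s) grid; the best grid cells (per candidate `w` for the full
#' model) are polished by Levenberg-Marquardt under bounds, and ties are
#' broken toward `w` closest to 0.5.
#'
#' @param responses numeric vector of rates, one per condition.
#' @param cond the matching condition table.
#' @param w_fixed `NULL` for the full model, or 0 / 1 for a submodel.
#' @param grid optional precomputed [ref_start_grid()] for `cond`.
#' @param extra_starts optional list of named parameter vectors
#'   (`a, mu, s, g, c, w`) to include as additional polish starts.
#' @param n_starts number of distinct-`w` grid starts polished for the full
#'   model.
#' @return list with `par` (named vector `a, mu, s, g, c, w`), `rss`, `r2`.
#' @export
fit_reference_frame <- function(responses, cond, w_fixed = NULL, grid = NULL,
                                extra_starts = NULL, n_starts = 3) {
  b <- ref_fit_bounds()
  full <- is.null(w_fixed)
  if (!full && !w_fixed %in% c(0, 1)) {
    stop("`w_fixed` must be 0 or 1", call. = FALSE)
  }
  n_par <- if (full) 6L else 5L
  if (nrow(cond) < n_par) {
    stop("fewer conditions than free parameters", call. = FALSE)
  }
  stopifnot(length(responses) == nrow(cond))
  if (is.null(grid)) grid <- ref_start_grid(cond)
  keep <- if (full) seq_len(nrow(grid$combos)) else which(grid$combos$w == w_fixed)
  prof <- profile_linear_fits(matrix(responses, nrow = 1),
                              grid$X[, keep, drop = FALSE], b$a, b$c)
  combos <- grid$combos[keep, , drop = FALSE]

  starts <- list()
  if (full) {
    # best grid cell within each candidate w, ranked by profiled rss
    best_by_w <- vapply(split(seq_len(nrow(combos)), combos$w),
                        function(ix) ix[which.min(prof$rss[1, ix])],
                        integer(1))
    best_by_w <- best_by_w[order(prof$rss[1, best_by_w])]
    for (k in utils::head(best_by_w, n_starts)) {
      starts[[length(starts) + 1L]] <-
        c(a = unname(prof$a[1, k]), mu = combos$mu[k], s = combos$s[k],
          g = 0, c = unname(prof$c[1, k]), w = combos$w[k])
    }
  } else {
    ord <- order(prof$rss[1, ])
    for (k in utils::head(ord, 2)) {
      starts[[length(starts) + 1L]] <-
        c(a = unname(prof$a[1, k]), mu = combos$mu[k], s = combos$s[k],
          g = 0, c = unname(prof$c[1, k]))
    }
  }
  for (st in extra_starts) {
    starts[[length(starts) + 1L]] <- st[c("a", "mu", "s", "g", "c",
                                          if (full) "w")]
  }

  par_names <- c("a", "mu", "s", "g", "c", if (full) "w")
  lower <- vapply(b[par_names], `[`, numeric(1), 1)
  upper <- vapply(b[par_names], `[`, numeric(1), 2)
  best <- NULL
  for (st in starts) {
    fit <- fit_bounded_ls(responses,
                          function(p) .ref_model(p, cond, w_fixed),
                          unlist(st)[par_names], lower, upper)
    better <- is.null(best) || fit$rss < best$rss - 1e-10 ||
      (full && abs(fit$rss - best$rss) <= 1e-10 &&
         abs(fit$par[["w"]] - 0.5) < abs(best$par[["w"]] - 0.5))
    if (better) best <- fit
  }
  par <- best$par
  if (!full) par <- c(par, w = w_fixed)
  list(par = par[c("a", "mu", "s", "g", "c", "w")],
       rss = best$rss, r2 = r_squared(responses, best$rss))
}

#' Nested F-test between the full model and a pure-frame submodel
#'
#' `F = (RSS_sub - RSS_full) / (RSS_full / (n - 6))` on 1 and `n - 6`
#' degrees of freedom. Degenerate cases: a (numerically) perfect full fit
#' gives `p = 0` when the submodel misfits and `p = 1` when both fits are
#' perfect. A submodel RSS below the full-model RSS beyond tolerance
#' signals an optimizer failure and raises an error.
#'
#' @param rss_full,rss_sub residual sums of squares (vectors allowed).
#' @param n number of conditions.
#' @param k_full number of free parameters in the full model (6).
#' @return vector of p-values.
#' @export
nested_f_test <- function(rss_full, rss_sub, n, k_full = 6) {
  stopifnot(n > k_full)
  tol <- 1e-8 * (1 + pmax(rss_full, rss_sub))
  if (any(rss_sub < rss_full - tol)) {
    stop("submodel RSS below full-model RSS: optimizer failure", call. = FALSE)
  }
  eps <- 1e-10 * (1 + rss_sub)
  num <- pmax(rss_sub - rss_full, 0)
  p <- ifelse(rss_full <= eps,
              ifelse(rss_sub <= eps, 1, 0),
              stats::pf(num / (rss_full / (n - k_full)), 1, n - k_full,
                        lower.tail = FALSE))
  p
}

#' Stepwise reference-frame classification
#'
#' Decision table over the two submodel tests at level `alpha`: both
#' pure-frame submodels rejected gives `intermediate`; only the hand
#' submodel rejected gives `eye`; only the eye submodel rejected gives
#' `hand`; neither rejected gives `indeterminate`.
#'
#' @param p_eye p-value of the test against the eye-centered submodel
#'   (`w = 1`).
#' @param p_hand p-value against the hand-centered submodel (`w = 0`).
#' @param alpha significance level (default 0.01).
#' @return character vector of classes.
#' @export
classify_unit <- function(p_eye, p_hand, alpha = 0.01) {
  eye_rej <- p_eye < alpha
  hand_rej <- p_hand < alpha
  ifelse(eye_rej & hand_rej, "intermediate",
         ifelse(hand_rej, "eye",
                ifelse(eye_rej, "hand", "indeterminate")))
}

#' Fit and classify a set of units on the delay task
#'
#' For each unit: fit both pure-frame submodels, then the full model (the
#' submodel solutions are included among the full-model starts, which
#' enforces the nesting inequality numerically), run both nested F-tests
#' and apply the stepwise decision table.
#'
#' @param units a unit table (typically the screened subset).
#' @param rates units x conditions matrix of responses.
#' @param cond the delay-task condition table.
#' @param alpha significance level for the F-tests.
#' @return a `data.frame` with one row per unit: fitted parameters, `r2`,
#'   `rss`, `p_eye`, `p_hand`, `class`.
#' @export
classify_reference_frames <- function(units, rates, cond, alpha = 0.01) {
  stopifnot(nrow(units) == nrow(rates), ncol(rates) == nrow(cond))
  grid <- ref_start_grid(cond)
  n <- nrow(units)
  res <- data.frame(unit_id = units$unit_id, node = units$node,
                    a = numeric(n), mu = numeric(n), s = numeric(n),
                    g = numeric(n), c = numeric(n), w = numeric(n),
                    r2 = numeric(n), rss = numeric(n),
                    p_eye = numeric(n), p_hand = numeric(n),
                    class = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    y <- rates[i, ]
    sub_eye <- fit_reference_frame(y, cond, w_fixed = 1, grid = grid)
    sub_hand <- fit_reference_frame(y, cond, w_fixed = 0, grid = grid)
    full <- fit_reference_frame(y, cond, grid = grid,
                                extra_starts = list(sub_eye$par, sub_hand$par))
    p_eye <- nested_f_test(full$rss, sub_eye$rss, nrow(cond))
    p_hand <- nested_f_test(full$rss, sub_hand$rss, nrow(cond))
    res[i, c("a", "mu", "s", "g", "c", "w")] <- as.list(full$par)
    res$r2[i] <- full$r2; res$rss[i] <- full$rss
    res$p_eye[i] <- p_eye; res$p_hand[i] <- p_hand
    res$class[i] <- classify_unit(p_eye, p_hand, alpha)
  }
  res
}

#' Summaries of a reference-frame distribution
#'
#' Class counts and percentages per node, the histogram-ready table of
#' classified units (indeterminate units are excluded from the weight
#' histogram but retained in the counts), and the median full-model `r2`
#' per weight bin, overall and for the best-fit (`r2 >= r2_threshold`)
#' subset.
#'
#' @param fits output of [classify_reference_frames()].
#' @param bin_width histogram bin width on `w`.
#' @param r2_threshold threshold defining the best-fit subset.
#' @return list with elements `units`, `class_counts`, `class_percent`,
#'   `included`, `r2_by_bin`.
#' @export
reference_frame_distribution <- function(fits, bin_width = 0.1,
                                         r2_threshold = 0.8) {
  if (nrow(fits) == 0) {
    warning("empty screened population: empty distribution")
    return(list(units = fits, class_counts = table(character()),
                class_percent = numeric(), included = 0,
                r2_by_bin = data.frame()))
  }
  counts <- table(node = fits$node, class = fits$class)
  pct <- 100 * prop.table(counts, margin = 1)
  classified <- fits[fits$class != "indeterminate", , drop = FALSE]
  bins <- bin_width * round(classified$w / bin_width)
  r2_by_bin <- do.call(rbind, lapply(split(classified, bins), function(d) {
    data.frame(w_bin = bin_width * round(d$w[1] / bin_width),
               n = nrow(d), median_r2 = stats::median(d$r2),
               median_r2_best = if (any(d$r2 >= r2_threshold))
                 stats::median(d$r2[d$r2 >= r2_threshold]) else NA_real_)
  }))
  list(units = classified, class_counts = counts, class_percent = pct,
       included = nrow(fits), r2_by_bin = r2_by_bin)
}
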