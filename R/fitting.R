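## Shared bounded least-squares machinery.
##
## Every fit in the package is a box-constrained nonlinear least-squares
## problem whose model is linear in the amplitude and baseline once the
## nonlinear parameters are fixed. Starts are therefore chosen by profiling
## (a, c) in closed form over a deterministic grid of the nonlinear
## parameters, and the best starts are polished with Levenberg-Marquardt
## under bounds (minpack.lm::nls.lm).

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Profile amplitude/baseline for models y ~ a * X[, k] + c.
# Y: n_units x m responses; X: m x K basis columns.
# Returns n x K matrices a, c, rss with (a, c) clamped to bounds (one
# alternation pass; adequate for start selection, the polish enforces
# bounds exactly).
profile_linear_fits <- function(Y, X, a_bounds, c_bounds) {
  m <- nrow(X)
  Sx <- colSums(X)
  Sxx <- colSums(X^2)
  Sy <- rowSums(Y)
  Syy <- rowSums(Y^2)
  Sxy <- Y %*% X
  denom <- m * Sxx - Sx^2
  flat <- denom <= 1e-10 * pmax(1, Sxx)  # (near-)constant basis column
  denom[flat] <- 1
  a <- sweep(m * Sxy - outer(Sy, Sx), 2, denom, "/")
  a[, flat] <- 0
  a <- .clamp(a, a_bounds[1], a_bounds[2])
  cc <- .clamp((Sy - sweep(a, 2, Sx, "*")) / m, c_bounds[1], c_bounds[2])
  a <- .clamp(sweep(Sxy - sweep(cc, 2, Sx, "*"), 2, Sxx, "/"),
              a_bounds[1], a_bounds[2])
  a[, flat] <- .clamp(0, a_bounds[1], a_bounds[2])
  rss <- Syy - 2 * a * Sxy - 2 * cc * Sy +
    sweep(a^2, 2, Sxx, "*") + 2 * a * cc * rep(1, nrow(Y)) %o% Sx + m * cc^2
  rss[rss < 0] <- 0
  list(a = a, c = cc, rss = rss)
}

# Levenberg-Marquardt under bounds; fn(par) returns model predictions.
fit_bounded_ls <- function(y, fn, start, lower, upper, maxiter = 150) {
  start <- .clamp(start, lower, upper)
  res <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) fn(p) - y,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-12, ptol = 1e-12))
  list(par = res$par, rss = res$deviance)
}

r_squared <- function(y, rss) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(0)
  1 - rss / sst
}
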