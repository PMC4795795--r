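#' Build a population of units tiling onset space
#'
#' Generates `N` onset values per onset dimension spanning `-3*sigma` to
#' `+3*sigma` degrees of eccentricity. Node kinds with a single tuning onset
#' (`u`) yield `N` units; node kinds with both a tuning onset `u` and a
#' modulation onset `v` yield the full `N x N` tiling with every `(u, v)`
#' pair exactly once. Gain slopes alternate between positive and negative
#' for adjacent units, starting positive, in unit-id order (row-major over
#' `(u, v)`, `v` varying fastest).
#'
#' Onsets are an evenly spaced deterministic grid by default, which keeps
#' unit counts in downstream screens stable and reproducible; a seeded
#' uniform-random mode is available for robustness checks.
#'
#' @param node a node kind understood by [unit_response()].
#' @param N onsets per dimension (`>= 2`).
#' @param sigma tuning length-scale in degrees; onsets span `[-3*sigma, 3*sigma]`.
#' @param A response amplitude passed through to the unit table.
#' @param sampling `"grid"` (default) or `"uniform_random"`.
#' @param seed integer seed, used only for `sampling = "uniform_random"`.
#' @return a unit table (see [unit_spec()]) with stable ids like `eye_007_022`.
#' @examples
#' nrow(build_population("hand_dyn", N = 30))  # 30
#' nrow(build_population("eye", N = 30))       # 900
#' @export
build_population <- function(node, N = 30, sigma = 15, A = 30,
                             sampling = c("grid", "uniform_random"),
                             seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(length(node) == 1L, N >= 2, sigma > 0)
  dual <- node_uses_modulation(node)
  onsets <- function() {
    if (sampling == "grid") {
      seq(-3 * sigma, 3 * sigma, length.out = N)
    } else {
      stats::runif(N, -3 * sigma, 3 * sigma)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  u_vals <- onsets()
  if (dual) {
    v_vals <- if (sampling == "grid") u_vals else onsets()
    grid <- expand.grid(v = v_vals, u = u_vals,
                        KEEP.OUT.ATTRS = FALSE)  # v fastest = row-major (u, v)
    iu <- rep(seq_len(N), each = N)
    iv <- rep(seq_len(N), times = N)
    ids <- sprintf("%s_%03d_%03d", node, iu, iv)
    u <- grid$u; v <- grid$v
  } else {
    ids <- sprintf("%s_%03d", node, seq_len(N))
    u <- u_vals; v <- NA_real_
  }
  n <- length(u)
  unit_spec(node = node, u = u, v = v,
            gain_sign = rep_len(c(1L, -1L), n),
            A = A, sigma = sigma, unit_id = ids)
}

#' Populations for a named network architecture
#'
#' The main network has three internal nodes: an eye-centered target node
#' gain-modulated by hand position (`eye`), a dynamic hand-centered node
#' tuned to the scaled displacement vector (`hand_dyn`), and an
#' eye-and-hand-centered node (`eye_hand`). The alternative architectures
#' swap these for the node kinds implied by rearrangements of the trajectory
#' equation: `rising` uses a static displacement node and a rising-scaled
#' eye-and-hand node; `two_sigmoid` uses five single-purpose nodes driven by
#' rising/falling scalings of `TE` and `HE`; `static_hand` replaces only the
#' dynamic hand-centered node by its static counterpart.
#'
#' @param network one of `"main"`, `"rising"`, `"two_sigmoid"`, `"static_hand"`.
#' @inheritParams build_population
#' @return a single unit table, nodes stacked.
#' @export
network_populations <- function(network = c("main", "rising", "two_sigmoid",
                                            "static_hand"),
                                N = 30, sigma = 15, A = 30,
                                sampling = "grid", seed = NULL) {
  network <- match.arg(network)
  nodes <- switch(network,
    main        = c("eye", "hand_dyn", "eye_hand"),
    rising      = c("eye", "hand_static", "eye_hand_rising"),
    two_sigmoid = c("te_gauss", "te_rising", "he_gauss", "he_falling",
                    "te_he_mixed"),
    static_hand = c("eye", "hand_static", "eye_hand"))
  do.call(rbind, lapply(nodes, build_population, N = N, sigma = sigma,
                        A = A, sampling = sampling, seed = seed))
}
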