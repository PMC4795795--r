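#' Screen and classify a population at one task time
#'
#' The full delay-period analysis chain applied at normalized time `t`:
#' simulate center-out screening responses, screen on the peak-location and
#' SVE criteria, simulate the 45-condition reference-frame task for the
#' accepted units, fit the full model and both pure-frame submodels, and
#' classify by nested F-tests. Noise (when `noise_sd > 0`) is drawn from
#' R's current random stream: seed the stream once per experiment for
#' end-to-end reproducibility, as [run_experiment()] does.
#'
#' @param units a unit table, e.g. from [network_populations()].
#' @param sigma task length-scale (degrees), shared with the populations.
#' @param noise_sd Gaussian response noise SD (rate units); 0 for noiseless.
#' @param sve_threshold screening threshold on spike variance explained.
#' @param alpha significance level of the classification F-tests.
#' @param eh_pairs eye/hand pairs of the reference-frame task.
#' @param t normalized task time at which responses are observed.
#' @param seed optional integer; if given, seeds the random stream first.
#' @return list: `screen` (screening report for all units), `fits`
#'   (classification table for accepted units), `screen_cond`, `delay_cond`.
#' @export
delay_period_analysis <- function(units, sigma = 15, noise_sd = 5,
                                  sve_threshold = 10, alpha = 0.01,
                                  eh_pairs = default_eh_pairs(sigma),
                                  t = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  screen_cond <- screening_task_conditions(sigma)
  delay_cond <- delay_task_conditions(sigma, eh_pairs)
  screen_rates <- add_noise(unit_response(units, screen_cond, t), noise_sd)
  screen <- screen_population(units, screen_rates, screen_cond$T,
                              sve_threshold)
  kept <- units[screen$accepted, , drop = FALSE]
  if (nrow(kept) == 0) {
    fits <- classify_reference_frames(kept,
                                      matrix(0, 0, nrow(delay_cond)),
                                      delay_cond, alpha)
  } else {
    delay_rates <- add_noise(unit_response(kept, delay_cond, t), noise_sd)
    fits <- classify_reference_frames(kept, delay_rates, delay_cond, alpha)
  }
  list(screen = screen, fits = fits,
       screen_cond = screen_cond, delay_cond = delay_cond)
}
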