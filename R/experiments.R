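#' Experiment configuration
#'
#' Collects every tunable of the simulation and analysis pipeline, with
#' defaults at the model's standard operating point: amplitude `A = 30`,
#' length-scale `sigma = 15` degrees, `N = 30` onsets per dimension on a
#' deterministic grid, response noise SD 5, SVE screening threshold 10 and
#' F-test level 0.01.
#'
#' @param A response amplitude (rate units).
#' @param sigma tuning/modulation length-scale (degrees).
#' @param N onsets per dimension.
#' @param sampling onset sampling mode, `"grid"` or `"uniform_random"`.
#' @param noise_sd Gaussian response noise SD.
#' @param seed integer seed expanded internally per experiment stage.
#' @param sve_threshold screening threshold on spike variance explained.
#' @param alpha F-test significance level.
#' @param eh_pairs eye/hand pairs of the reference-frame task (`NULL` for
#'   the defaults).
#' @param time_points movement-epoch times for the reclassification
#'   analysis.
#' @param hybrid_weights composition weights of the hybrid gradient
#'   population.
#' @param gradient_t_step time step of the gradient analysis.
#' @return a list of class `reachframes_config`.
#' @export
experiment_config <- function(A = 30, sigma = 15, N = 30, sampling = "grid",
                              noise_sd = 5, seed = 1L, sve_threshold = 10,
                              alpha = 0.01, eh_pairs = NULL,
                              time_points = c(0, 0.25, 0.5, 0.75, 1),
                              hybrid_weights = c(eye = 0.25, hand_dyn = 0.5,
                                                 eye_hand = 0.25),
                              gradient_t_step = 0.1) {
  stopifnot(A > 0, sigma > 0, N >= 2, noise_sd >= 0, sve_threshold >= 0,
            alpha > 0, alpha < 1, gradient_t_step > 0)
  structure(list(A = A, sigma = sigma, N = N, sampling = sampling,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 sve_threshold = sve_threshold, alpha = alpha,
                 eh_pairs = eh_pairs, time_points = time_points,
                 hybrid_weights = hybrid_weights,
                 gradient_t_step = gradient_t_step),
            class = "reachframes_config")
}

.experiment_names <- c("delay_noiseless", "delay_noisy", "movement_dynamics",
                       "gradient_pure_hand", "gradient_hybrid",
                       "variant_rising", "variant_two_sigmoid",
                       "variant_static_hand")

# screened subset of a population, on noiseless delay-period center-out
# responses (the screen used by the gradient experiments)
.screened_units <- function(units, cfg) {
  screen_cond <- screening_task_conditions(cfg$sigma)
  rates <- unit_response(units, screen_cond, t = 0)
  screen <- screen_population(units, rates, screen_cond$T, cfg$sve_threshold)
  list(units = units[screen$accepted, , drop = FALSE], screen = screen)
}

#' Run a named, seeded experiment
#'
#' Orchestrates one of the package's standard simulations end to end and
#' returns a result bundle; outputs are identical for identical
#' `(name, config)` including the seed.
#'
#' * `delay_noiseless`, `delay_noisy`: the delay-period reference-frame
#'   distribution of the main network, without/with response noise.
#' * `movement_dynamics`: time-resolved reclassification across movement.
#' * `gradient_pure_hand`, `gradient_hybrid`: gradient analysis of the pure
#'   dynamic hand-centered node, and of the 0.25/0.50/0.25 hybrid of the
#'   three main nodes, across the whole task.
#' * `variant_rising`, `variant_two_sigmoid`: delay-period distributions of
#'   the two alternative architectures.
#' * `variant_static_hand`: hybrid gradient analysis with the dynamic
#'   hand-centered node replaced by its static counterpart (delay and
#'   movement epochs; this architecture defines no pre-target responses).
#'
#' @param name experiment name (see Details).
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the population manifest,
#'   report tables and a `summary.json` are written there.
#' @return a list: `name`, `config`, `population`, experiment-specific
#'   tables, and a JSON-ready `summary`.
#' @export
run_experiment <- function(name, config = experiment_config(),
                           out_dir = NULL) {
  name <- match.arg(name, .experiment_names)
  cfg <- config
  set.seed(cfg$seed)
  eh <- if (is.null(cfg$eh_pairs)) default_eh_pairs(cfg$sigma) else cfg$eh_pairs
  pop_for <- function(network) {
    network_populations(network, N = cfg$N, sigma = cfg$sigma, A = cfg$A,
                        sampling = cfg$sampling)
  }
  res <- switch(name,
    delay_noiseless = ,
    delay_noisy = {
      units <- pop_for("main")
      sd <- if (name == "delay_noisy") cfg$noise_sd else 0
      an <- delay_period_analysis(units, sigma = cfg$sigma, noise_sd = sd,
                                  sve_threshold = cfg$sve_threshold,
                                  alpha = cfg$alpha, eh_pairs = eh)
      dist <- reference_frame_distribution(an$fits)
      list(population = units, screen = an$screen, fits = an$fits,
           distribution = dist,
           summary = .class_summary(an$fits))
    },
    variant_rising = ,
    variant_two_sigmoid = {
      units <- pop_for(sub("^variant_", "", name))
      an <- delay_period_analysis(units, sigma = cfg$sigma,
                                  noise_sd = cfg$noise_sd,
                                  sve_threshold = cfg$sve_threshold,
                                  alpha = cfg$alpha, eh_pairs = eh)
      dist <- reference_frame_distribution(an$fits)
      list(population = units, screen = an$screen, fits = an$fits,
           distribution = dist,
           summary = .class_summary(an$fits))
    },
    movement_dynamics = {
      units <- pop_for("main")
      ev <- evolve_classification(units, sigma = cfg$sigma,
                                  noise_sd = cfg$noise_sd,
                                  sve_threshold = cfg$sve_threshold,
                                  alpha = cfg$alpha, eh_pairs = eh,
                                  time_points = cfg$time_points)
      list(population = units, trajectory = ev$trajectory,
           trends = ev$trends, fits = ev$fits,
           summary = list(trends = ev$trends))
    },
    gradient_pure_hand = {
      units <- build_population("hand_dyn", N = cfg$N, sigma = cfg$sigma,
                                A = cfg$A, sampling = cfg$sampling)
      sc <- .screened_units(units, cfg)
      series <- gradient_series(sc$units,
                                time_points = seq(-2, 1,
                                                  by = cfg$gradient_t_step))
      list(population = units, screen = sc$screen, series = series,
           epochs = epoch_samples(series),
           summary = list(n_units = nrow(sc$units)))
    },
    gradient_hybrid = {
      units <- pop_for("main")
      sc <- .screened_units(units, cfg)
      series <- gradient_series(sc$units,
                                time_points = seq(-2, 1,
                                                  by = cfg$gradient_t_step),
                                weights = cfg$hybrid_weights)
      list(population = units, screen = sc$screen, series = series,
           epochs = epoch_samples(series),
           summary = list(n_units = nrow(sc$units)))
    },
    variant_static_hand = {
      units <- pop_for("static_hand")
      sc <- .screened_units(units, cfg)
      w <- cfg$hybrid_weights
      names(w)[names(w) == "hand_dyn"] <- "hand_static"
      series <- gradient_series(sc$units,
                                time_points = seq(-1, 1,
                                                  by = cfg$gradient_t_step),
                                weights = w)
      list(population = units, screen = sc$screen, series = series,
           epochs = epoch_samples(series, epochs = c(go = 0, offset = 1)),
           summary = list(n_units = nrow(sc$units)))
    })
  res <- c(list(name = name, config = unclass(cfg)), res)
  if (!is.null(out_dir)) .write_bundle(res, out_dir)
  invisible(res)
}

.class_summary <- function(fits) {
  nodes <- sort(unique(fits$node))
  per_node <- lapply(nodes, function(nd) {
    d <- fits[fits$node == nd, ]
    counts <- vapply(c("eye", "hand", "intermediate", "indeterminate"),
                     function(cl) sum(d$class == cl), numeric(1))
    list(included = nrow(d), counts = as.list(counts),
         percent = as.list(100 * counts / max(1, nrow(d))))
  })
  names(per_node) <- nodes
  list(included_total = nrow(fits), per_node = per_node)
}

.write_bundle <- function(res, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  wr <- function(obj, file) {
    utils::write.csv(obj, file.path(out_dir, file), row.names = FALSE)
  }
  wr(res$population, "population.csv")
  if (!is.null(res$screen)) wr(res$screen, "screening.csv")
  if (!is.null(res$fits) && is.data.frame(res$fits)) wr(res$fits, "fits.csv")
  if (!is.null(res$trajectory)) wr(res$trajectory, "trajectory.csv")
  if (!is.null(res$trends)) wr(res$trends, "trends.csv")
  if (!is.null(res$series)) wr(res$series, "gradients.csv")
  if (!is.null(res$epochs)) wr(res$epochs, "epoch_samples.csv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
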