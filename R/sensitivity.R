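#' Default parameter ranges for the global sensitivity study
#'
#' The reference ranges spanning an order of magnitude around the study
#' parameter values: `k1`, `h`, `A`, `B` in `[0.001, 0.01]`, `k2` in
#' `[0, 0.01]`, and the Hill exponent `hill_k` in `[1, 5]`.
#'
#' @return A tibble with columns `name`, `min`, `max`.
#' @export
sensitivity_ranges <- function() {
  tibble(
    name = c("k1", "k2", "h", "hill_k", "A", "B"),
    min = c(0.001, 0.000, 0.001, 1, 0.001, 0.001),
    max = c(0.010, 0.010, 0.010, 5, 0.010, 0.010)
  )
}

check_ranges <- function(ranges) {
  stopifnot(is.data.frame(ranges),
            all(c("name", "min", "max") %in% names(ranges)))
  if (any(ranges$min > ranges$max)) abort("Each range needs `min` <= `max`.")
  bad <- setdiff(ranges$name, valid_sweep_params())
  if (length(bad)) {
    abort(sprintf("Unknown parameter(s): %s. Valid names: %s.",
                  paste(bad, collapse = ", "),
                  paste(valid_sweep_params(), collapse = ", ")))
  }
  invisible(ranges)
}

#' Latin hypercube sample over parameter ranges
#'
#' Draws a stratified sample: for each parameter, the `n_samples` draws
#' occupy the `n_samples` equal-width strata of its range exactly once,
#' uniformly within each stratum. Deterministic for a fixed seed.
#'
#' @param ranges Tibble with columns `name`, `min`, `max` (see
#'   [sensitivity_ranges()]).
#' @param n_samples Number of rows to draw (>= 1).
#' @param seed Integer RNG seed.
#' @return A tibble with `n_samples` rows and one column per parameter.
#' @examples
#' lhs_sample(sensitivity_ranges(), n_samples = 5, seed = 1)
#' @export
lhs_sample <- function(ranges, n_samples, seed = 1L) {
  check_ranges(ranges)
  stopifnot(n_samples >= 1)
  unit <- withr::with_seed(seed, lhs::randomLHS(n_samples, nrow(ranges)))
  scaled <- sweep(unit, 2L, ranges$max - ranges$min, `*`)
  scaled <- sweep(scaled, 2L, ranges$min, `+`)
  colnames(scaled) <- ranges$name
  as_tibble(scaled)
}

# Simulate the study output once per sample row; rows that fail to
# integrate are dropped and counted. Returns list(values = runs x times
# matrix (or runs-vector for "J"), n_failed).
run_samples <- function(params, schedule, samples, times, output,
                        weights = NULL, rtol = 1e-8, atol = 1e-10) {
  pk_only <- output == "c"
  run_one <- function(row) {
    p_i <- params
    for (nm in names(row)) p_i <- set_model_param(p_i, nm, row[[nm]])
    if (pk_only) {
      integrate_pk(p_i$pk, schedule, times, rtol = rtol, atol = atol)
    } else {
      traj <- simulate_chemo(p_i, schedule, t_end = max(times),
                             n_steps = length(times) - 1L,
                             rtol = rtol, atol = atol, weights = weights)
      if (output == "N") rowSums(as.matrix(
        as_tibble(traj)[grep("^N_", names(traj), value = TRUE)]))
      else evaluate_objective(traj, weights)
    }
  }
  runs <- purrr::map(seq_len(nrow(samples)), function(i) {
    tryCatch(run_one(as.list(samples[i, ])),
             error = function(e) {
               warn(sprintf("Sample %d excluded: %s", i,
                            conditionMessage(e)))
               NULL
             })
  })
  ok <- !purrr::map_lgl(runs, is.null)
  values <- if (output == "J") unlist(runs[ok]) else
    do.call(rbind, runs[ok])
  list(values = values, n_failed = sum(!ok))
}

#' Per-time sensitivity envelope of the concentration (or cell) curve
#'
#' Draws a Latin hypercube sample over the varied ranges, substitutes each
#' row into the baseline bundle, simulates, and summarizes the resulting
#' family of curves pointwise in time by min, 5%/95% quantiles, mean,
#' median and max. With `output = "c"` only the PK subsystem is integrated:
#' the concentration equation does not involve the tumor states, so this is
#' exact and makes the concentration envelope provably independent of `A`,
#' `B` and `hill_k`.
#'
#' Individual simulations that fail (e.g. blow-up under extreme draws) are
#' excluded with a warning and counted in the `n_failed` attribute.
#'
#' @param params Baseline [model_params()].
#' @param schedule A [dose_schedule()].
#' @param ranges Ranges to vary jointly (tibble `name`/`min`/`max`); an
#'   empty tibble varies nothing and all bands collapse onto the baseline.
#' @param n_samples Latin hypercube rows (default 100).
#' @param seed RNG seed.
#' @param t_end,n_steps Reporting grid (unit spacing by default).
#' @param output `"c"` (concentration, default) or `"N"` (total cells).
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `chemo_envelope` with columns `time`, `min`,
#'   `q05`, `mean`, `median`, `q95`, `max`; attributes `n_samples`,
#'   `n_failed`, `output`, `baseline` (the baseline curve) and `samples`.
#' @examples
#' defs <- study_defaults()
#' rng <- dplyr::filter(sensitivity_ranges(), name %in% c("k1", "h"))
#' env <- sensitivity_envelope(defs$params, defs$schedule, rng,
#'                             n_samples = 10, t_end = 50)
#' @export
sensitivity_envelope <- function(params, schedule,
                                 ranges = sensitivity_ranges(),
                                 n_samples = 100, seed = 1L, t_end = 500,
                                 n_steps = max(2L, round(t_end)),
                                 output = c("c", "N"),
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "dose_schedule"))
  output <- match.arg(output)
  times <- seq(0, t_end, length.out = n_steps + 1L)
  validate_dose_on_grid(schedule, times)
  baseline <- if (output == "c") {
    integrate_pk(params$pk, schedule, times, rtol, atol)
  } else {
    traj <- simulate_chemo(params, schedule, t_end = t_end,
                           n_steps = n_steps, rtol = rtol, atol = atol)
    rowSums(as.matrix(as_tibble(traj)[grep("^N_", names(traj))]))
  }
  if (nrow(ranges) == 0L || n_samples == 0L) {
    vals <- matrix(baseline, nrow = 1L)
    samples <- tibble()
    n_failed <- 0L
  } else {
    check_ranges(ranges)
    samples <- lhs_sample(ranges, n_samples, seed)
    res <- run_samples(params, schedule, samples, times, output,
                       rtol = rtol, atol = atol)
    vals <- res$values
    n_failed <- res$n_failed
    if (is.null(vals) || nrow(vals) == 0L) {
      abort("All sensitivity samples failed to simulate.")
    }
  }
  bands <- tibble(
    time = times,
    min = apply(vals, 2L, min),
    q05 = apply(vals, 2L, quantile, probs = 0.05, names = FALSE),
    mean = colMeans(vals),
    median = apply(vals, 2L, median),
    q95 = apply(vals, 2L, quantile, probs = 0.95, names = FALSE),
    max = apply(vals, 2L, max)
  )
  structure(bands,
            class = c("chemo_envelope", class(tibble())),
            n_samples = if (nrow(samples)) n_samples else 1L,
            n_failed = n_failed, output = output,
            baseline = baseline, samples = samples)
}

#' Rank parameters by one-at-a-time sensitivity of the concentration curve
#'
#' For each parameter in `ranges`, draws a one-dimensional Latin hypercube
#' over its range (others held at baseline), simulates, and scores the
#' parameter by the time-integrated envelope width of the output curve
#' normalized by the time-integrated baseline:
#' \deqn{score = \int_0^{T} (max_i y_i(t) - min_i y_i(t)) dt /
#'   \int_0^{T} y_{base}(t) dt.}
#' This mirrors the visual band-width comparison of envelope plots. A
#' parameter the output does not depend on scores exactly 0. For
#' `output = "J"` the score is instead the spread of the objective,
#' `(max J - min J) / J_base`.
#'
#' @inheritParams sensitivity_envelope
#' @param output `"c"` (default), `"N"`, or `"J"`.
#' @return A tibble of class `chemo_ranking` with columns `parameter`,
#'   `score`, `rank`, sorted by descending score.
#' @examples
#' defs <- study_defaults()
#' rng <- dplyr::filter(sensitivity_ranges(), name %in% c("k1", "A"))
#' rank_parameters(defs$params, defs$schedule, rng,
#'                 n_samples = 10, t_end = 50)
#' @export
rank_parameters <- function(params, schedule,
                            ranges = sensitivity_ranges(),
                            n_samples = 100, seed = 1L, t_end = 500,
                            n_steps = max(2L, round(t_end)),
                            output = c("c", "N", "J"),
                            rtol = 1e-8, atol = 1e-10) {
  output <- match.arg(output)
  check_ranges(ranges)
  times <- seq(0, t_end, length.out = n_steps + 1L)
  weights <- objective_weights(p = rep(1, params$tumor$n),
                               q = rep(1, params$tumor$n), b = 1,
                               t_horizon = t_end)
  baseline <- switch(output,
    c = integrate_pk(params$pk, schedule, times, rtol, atol),
    N = {
      traj <- simulate_chemo(params, schedule, t_end = t_end,
                             n_steps = n_steps, rtol = rtol, atol = atol)
      rowSums(as.matrix(as_tibble(traj)[grep("^N_", names(traj))]))
    },
    J = {
      traj <- simulate_chemo(params, schedule, t_end = t_end,
                             n_steps = n_steps, rtol = rtol, atol = atol,
                             weights = weights)
      evaluate_objective(traj, weights)
    })
  scores <- purrr::map_dbl(seq_len(nrow(ranges)), function(i) {
    rng_i <- ranges[i, ]
    samples <- lhs_sample(rng_i, n_samples, seed)
    res <- run_samples(params, schedule, samples, times, output,
                       weights = weights, rtol = rtol, atol = atol)
    if (output == "J") {
      (max(res$values) - min(res$values)) / baseline
    } else {
      width <- apply(res$values, 2L, max) - apply(res$values, 2L, min)
      pracma::trapz(times, width) / pracma::trapz(times, baseline)
    }
  })
  out <- tibble(parameter = ranges$name, score = scores)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$parameter)
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("chemo_ranking", class(tibble())),
            n_samples = n_samples, output = output, seed = seed)
}

#' Write an envelope to CSV
#'
#' Columns `time,min,q05,mean,median,q95,max`.
#'
#' @param env A `chemo_envelope`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "chemo_envelope"))
  readr::write_csv(
    as_tibble(env)[c("time", "min", "q05", "mean", "median", "q95", "max")],
    path)
  invisible(path)
}

#' Write a parameter ranking to CSV
#'
#' Columns `parameter,score,rank`.
#'
#' @param ranking A `chemo_ranking`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ranking, path) {
  stopifnot(inherits(ranking, "chemo_ranking"))
  readr::write_csv(as_tibble(ranking)[c("parameter", "score", "rank")], path)
  invisible(path)
}
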