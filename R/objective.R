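#' Evaluate the L1-type therapy objective on a trajectory
#'
#' Computes \eqn{J = p N(T) + \int_0^T (q N(t) + b u(t)) dt} by composite
#' quadrature on the trajectory's reporting grid. The terminal term weights
#' the tumor burden at the end of the therapy interval; the running term
#' penalizes intermediate burden and, through `b u(t)`, cumulative dose as
#' an indirect toxicity proxy.
#'
#' @param traj A `chemo_trajectory` covering `[0, T]`; the grid must contain
#'   `T = weights$t_horizon`.
#' @param weights An [objective_weights()]; defaults to the weights stored
#'   on the trajectory.
#' @param rule Quadrature rule for the running integral: composite
#'   `"trapezoid"` (default) or composite `"simpson"` as a cross-check.
#'   The integrand is smooth and the grid uniform, so the two agree
#'   closely.
#' @return Scalar J.
#' @seealso [objective_terms()] for the terminal/running decomposition,
#'   [sweep_objective()] for parameter sweeps.
#' @examples
#' defs <- study_defaults()
#' traj <- simulate_chemo(defs$params, defs$schedule, t_end = 100)
#' evaluate_objective(traj, objective_weights(t_horizon = 100))
#' @export
evaluate_objective <- function(traj, weights = NULL,
                               rule = c("trapezoid", "simpson")) {
  terms <- objective_terms(traj, weights, rule = match.arg(rule))
  terms$total
}

#' Terminal and running components of the objective
#'
#' @inheritParams evaluate_objective
#' @return A one-row tibble with columns `terminal`, `running`, `total`
#'   (`total = terminal + running` exactly).
#' @export
objective_terms <- function(traj, weights = NULL,
                            rule = c("trapezoid", "simpson")) {
  stopifnot(inherits(traj, "chemo_trajectory"))
  rule <- match.arg(rule)
  weights <- weights %||% attr(traj, "weights")
  stopifnot(inherits(weights, "objective_weights"))
  T_ <- weights$t_horizon
  if (max(traj$time) < T_ - 1e-9) {
    abort(sprintf("Trajectory ends at t = %g, before the horizon T = %g.",
                  max(traj$time), T_))
  }
  keep <- traj$time <= T_ + 1e-9
  times <- traj$time[keep]
  if (abs(times[length(times)] - T_) > 1e-8 * max(1, T_)) {
    abort("The trajectory grid must contain the horizon T as a grid point.")
  }
  n_cols <- grep("^N_", names(traj), value = TRUE)
  n_mat <- as.matrix(as_tibble(traj)[keep, n_cols, drop = FALSE])
  if (length(weights$p) != ncol(n_mat) || length(weights$q) != ncol(n_mat)) {
    abort("`weights$p` and `weights$q` must have one entry per compartment.")
  }
  integrand <- drop(n_mat %*% weights$q) + weights$b * traj$u[keep]
  running <- switch(rule,
                    trapezoid = pracma::trapz(times, integrand),
                    simpson = simpson_tab(times, integrand))
  terminal <- sum(weights$p * n_mat[nrow(n_mat), ])
  tibble(terminal = terminal, running = running,
         total = terminal + running)
}

# Composite Simpson on a uniform tabulated grid; the final interval of an
# even-length grid falls back to one trapezoid panel.
simpson_tab <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-8 * h[1]) {
    abort("Simpson quadrature requires a uniform grid.")
  }
  h <- h[1]
  m <- if (n %% 2L == 1L) n else n - 1L  # odd number of points => even panels
  idx <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1; w[m] <- 1
  out <- h / 3 * sum(w * y[idx])
  if (m < n) out <- out + h * (y[n - 1L] + y[n]) / 2
  out
}

#' Sweep a model parameter and re-evaluate the objective
#'
#' Runs one simulation and one objective evaluation per grid value of a
#' scalar model parameter, holding everything else fixed. Rows are returned
#' in the order of the input grid.
#'
#' @param params A [model_params()] baseline bundle.
#' @param schedule A [dose_schedule()].
#' @param param Name of the parameter to sweep; one of `k1`, `k2`, `h`,
#'   `e0`, `emax`, `ec50`, `hill_k`, `A`, `B` (the last two address the
#'   scalar one-compartment matrices).
#' @param values Non-empty numeric grid.
#' @param weights An [objective_weights()]; defaults to unit weights over
#'   `[0, t_end]`.
#' @param t_end,n_steps,rtol,atol Passed to [simulate_chemo()].
#' @return A tibble of class `chemo_sweep` with columns `param_value`, `J`
#'   and attribute `parameter`.
#' @examples
#' defs <- study_defaults()
#' sweep_objective(defs$params, defs$schedule, "k2",
#'                 values = c(0.0004, 0.004), t_end = 50)
#' @export
sweep_objective <- function(params, schedule, param, values, weights = NULL,
                            t_end = 500, n_steps = max(2L, round(t_end)),
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"), length(values) >= 1L)
  weights <- weights %||% objective_weights(
    p = rep(1, params$tumor$n), q = rep(1, params$tumor$n), b = 1,
    t_horizon = t_end)
  js <- purrr::map_dbl(values, function(v) {
    p_i <- set_model_param(params, param, v)
    traj <- simulate_chemo(p_i, schedule, t_end = t_end, n_steps = n_steps,
                           rtol = rtol, atol = atol, weights = weights)
    evaluate_objective(traj, weights)
  })
  structure(tibble(param_value = as.double(values), J = js),
            class = c("chemo_sweep", class(tibble())),
            parameter = param)
}

valid_sweep_params <- function() {
  c("k1", "k2", "h", "e0", "emax", "ec50", "hill_k", "A", "B")
}

# Substitute a named scalar parameter into a model_params bundle.
# hill_k draws from continuous samplers are rounded to the nearest integer
# >= 1, as the Hill exponent is integer-valued.
set_model_param <- function(params, name, value) {
  valid <- valid_sweep_params()
  if (!name %in% valid) {
    abort(sprintf("Unknown parameter `%s`. Valid names: %s.",
                  name, paste(valid, collapse = ", ")))
  }
  if (name %in% c("A", "B") && params$tumor$n != 1L) {
    abort("Scalar sweeps of `A`/`B` are supported for one compartment only.")
  }
  pk <- params$pk; pd <- params$pd; tum <- params$tumor
  switch(name,
         k1 = { pk <- pk_params(value, pk$k2, pk$h) },
         k2 = { pk <- pk_params(pk$k1, value, pk$h) },
         h = { pk <- pk_params(pk$k1, pk$k2, value) },
         e0 = { pd <- pd_params(value, pd$emax, pd$ec50, pd$hill_k) },
         emax = { pd <- pd_params(pd$e0, value, pd$ec50, pd$hill_k) },
         ec50 = { pd <- pd_params(pd$e0, pd$emax, value, pd$hill_k) },
         hill_k = { pd <- pd_params(pd$e0, pd$emax, pd$ec50,
                                    max(1L, round(value))) },
         A = { tum <- tumor_params(matrix(value), tum$b_matrix) },
         B = { tum <- tumor_params(tum$a_matrix, matrix(value)) })
  model_params(tumor = tum, pk = pk, pd = pd, n0 = params$n0,
               effect_model = params$effect_model)
}

#' Write a sweep table to CSV
#'
#' Columns `param_value,J`.
#'
#' @param sweep A `chemo_sweep`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "chemo_sweep"))
  readr::write_csv(as_tibble(sweep)[c("param_value", "J")], path)
  invisible(path)
}
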