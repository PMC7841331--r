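#' Simulate the coupled tumor/PK dynamics
#'
#' Integrates the coupled system
#' \deqn{dN/dt = (A + s(c) B) N, \quad N(0) = n_0}
#' \deqn{dc/dt = -(k_1 + k_2 u(t)) c + h u(t), \quad c(0) = 0}
#' with an adaptive explicit Runge-Kutta 4(5) scheme and reports the
#' solution on a uniform grid of `n_steps + 1` time points over
#' `[0, t_end]`. The reporting grid, not the solver's internal steps,
#' defines the rows of the returned trajectory; refining `n_steps` only
#' changes where the dense solution is sampled.
#'
#' The system is non-stiff at typical parameter values. A blow-up guard
#' aborts with a diagnostic naming the divergent state if any state exceeds
#' 1e12 in magnitude (reachable with strongly negative `k2`).
#'
#' @param params A [model_params()] bundle.
#' @param schedule A [dose_schedule()]; rejected if it is negative anywhere
#'   on the reporting grid.
#' @param t_end Simulation horizon (> 0). Default 500 time units.
#' @param n_steps Number of reporting intervals (>= 2); default `t_end`
#'   rounded, i.e. unit spacing.
#' @param rtol,atol Solver tolerances.
#' @param weights Optional [objective_weights()] used for the
#'   `running_cost` column `q * N(t) + b * u(t)`; defaults to unit weights.
#'
#' @return A tibble of class `chemo_trajectory` with columns `time`, `c`,
#'   `u`, `running_cost` and `N_1` ... `N_n`, plus attributes `params`,
#'   `schedule` and `weights`.
#' @examples
#' defs <- study_defaults()
#' traj <- simulate_chemo(defs$params, defs$schedule, t_end = 100)
#' head(traj)
#' @export
simulate_chemo <- function(params, schedule, t_end = 500,
                           n_steps = max(2L, round(t_end)),
                           rtol = 1e-8, atol = 1e-10, weights = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "dose_schedule"))
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (n_steps < 2) abort("`n_steps` must be at least 2.")
  if (rtol <= 0 || atol <= 0) abort("Tolerances must be positive.")
  weights <- weights %||% objective_weights(
    p = rep(1, params$tumor$n), q = rep(1, params$tumor$n), b = 1,
    t_horizon = t_end)
  if (length(weights$q) != params$tumor$n) {
    abort("`weights$q` must have one entry per compartment.")
  }

  times <- seq(0, t_end, length.out = n_steps + 1L)
  validate_dose_on_grid(schedule, times)

  n <- params$tumor$n
  y0 <- c(params$n0, 0)
  state_names <- c(paste0("N_", seq_len(n)), "c")

  rhs <- function(t, y, parms) {
    if (any(!is.finite(y)) || max(abs(y)) > 1e12) {
      bad <- state_names[which.max(abs(replace(y, !is.finite(y), Inf)))]
      abort(sprintf(
        "Simulation diverged: state `%s` exceeded the 1e12 blow-up guard near t = %g.",
        bad, t))
    }
    u <- eval_dose(schedule, t)
    cc <- max(y[n + 1L], 0)  # clamp solver round-off below zero
    s <- drug_effect(cc, params$pd, params$effect_model)
    list(c(tumor_rate(y[seq_len(n)], s, params$tumor),
           pk_rate(y[n + 1L], u, params$pk)))
  }

  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || any(!is.finite(sol[, -1]))) {
    abort("Simulation failed: the solver did not reach `t_end` with finite states.")
  }

  n_mat <- sol[, 1L + seq_len(n), drop = FALSE]
  c_vec <- pmax(sol[, n + 2L], 0)
  u_vec <- eval_dose(schedule, times)
  running <- drop(n_mat %*% weights$q) + weights$b * u_vec

  out <- tibble(time = times, c = c_vec, u = u_vec, running_cost = running)
  colnames(n_mat) <- paste0("N_", seq_len(n))
  out <- dplyr::bind_cols(out, as_tibble(n_mat))
  new_chemo_trajectory(out, params, schedule, weights)
}

new_chemo_trajectory <- function(data, params, schedule, weights) {
  structure(data,
            class = c("chemo_trajectory", class(tibble())),
            params = params, schedule = schedule, weights = weights)
}

#' @export
print.chemo_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<chemo_trajectory> %d time points over [%g, %g], %d compartment(s)\n",
              nrow(x), min(x$time), max(x$time), p$tumor$n))
  NextMethod()
}

# Fast path for concentration-only analyses: dc/dt never involves N, so the
# PK subsystem can be integrated on its own (exact, and much cheaper).
integrate_pk <- function(pk, schedule, times, rtol = 1e-8, atol = 1e-10) {
  rhs <- function(t, y, parms) {
    if (!is.finite(y) || abs(y) > 1e12) {
      abort(sprintf(
        "Simulation diverged: state `c` exceeded the 1e12 blow-up guard near t = %g.",
        t))
    }
    list(pk_rate(y, eval_dose(schedule, t), pk))
  }
  sol <- deSolve::ode(y = 0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || any(!is.finite(sol[, 2L]))) {
    abort("PK integration failed to reach the end of the time grid.")
  }
  pmax(sol[, 2L], 0)
}

#' Closed-form solution of a constant-coefficient linear system
#'
#' Evaluates \eqn{x(t) = e^{At} [x_0 + \int_0^t e^{-A\tau} B u(\tau) d\tau]}
#' by matrix exponential and adaptive quadrature. This is the textbook
#' variation-of-constants solution of \eqn{dx/dt = A x + B u(t)}; it serves
#' as an independent oracle for linear specializations of the simulator
#' (e.g. the concentration equation when `k2 = 0`).
#'
#' The forcing integral is evaluated with a 96-node Gauss-Legendre rule on
#' `[0, t]`, which is effectively exact for the smooth integrands arising
#' from bounded inputs.
#'
#' @param a_matrix n x n constant matrix.
#' @param b_matrix n x m constant input matrix.
#' @param x0 Initial state, length n.
#' @param u A function of time returning the m-vector (or scalar) input;
#'   must be integrable on `[0, max(t)]`.
#' @param t Numeric vector of evaluation times (>= 0).
#' @return A matrix with `length(t)` rows and n columns (dropped to a
#'   vector when `length(t) == 1`).
#' @examples
#' # pure integrator: x' = u, u = 1
#' closed_form_lti(matrix(0), matrix(1), 0, function(t) 1, t = 5)
#' @export
closed_form_lti <- function(a_matrix, b_matrix, x0, u, t) {
  a_matrix <- as.matrix(a_matrix)
  b_matrix <- as.matrix(b_matrix)
  n <- nrow(a_matrix)
  stopifnot(ncol(a_matrix) == n, nrow(b_matrix) == n, length(x0) == n,
            is.function(u), all(t >= 0))
  expm <- function(m) as.matrix(Matrix::expm(m))
  one_time <- function(tt) {
    if (tt == 0) return(as.double(x0))
    gl <- pracma::gaussLegendre(96, 0, tt)
    forced <- rep(0, n)
    for (j in seq_along(gl$x)) {
      tau <- gl$x[j]
      forced <- forced + gl$w[j] *
        drop(expm(-a_matrix * tau) %*% (b_matrix %*% cbind(u(tau))))
    }
    drop(expm(a_matrix * tt) %*% (x0 + forced))
  }
  out <- vapply(t, one_time, numeric(n))
  out <- if (n == 1L) matrix(out, ncol = 1L) else base::t(out)
  if (length(t) == 1L) drop(out) else out
}

#' Write a trajectory to CSV
#'
#' Deterministic column order `time,c,u,running_cost,N_1..N_n`.
#'
#' @param traj A `chemo_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "chemo_trajectory"))
  n_cols <- grep("^N_", names(traj), value = TRUE)
  readr::write_csv(as_tibble(traj)[c("time", "c", "u", "running_cost", n_cols)],
                   path)
  invisible(path)
}
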