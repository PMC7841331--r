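#' Pharmacodynamic (effect) parameters
#'
#' Bundles the parameters of the saturating concentration-effect curves used
#' throughout the package: the hyperbolic Emax model
#' \eqn{s(c) = E_0 + E_{max} c / (EC_{50} + c)} and its sigmoid Hill
#' generalization \eqn{s(c) = E_0 + E_{max} c^k / (EC_{50}^k + c^k)}.
#'
#' @param e0 Baseline efficacy at zero concentration (effect units, >= 0).
#' @param emax Maximum attainable efficacy above baseline (effect units, >= 0).
#' @param ec50 Potency: the concentration producing half-maximal effect
#'   (concentration units, > 0).
#' @param hill_k Positive integer Hill exponent; `hill_k = 1` recovers the
#'   Emax model exactly.
#'
#' @return An object of class `pd_params`.
#' @seealso [drug_effect()]
#' @examples
#' pd_params(e0 = 0, emax = 100, ec50 = 15)
#' @export
pd_params <- function(e0 = 0, emax = 100, ec50 = 15, hill_k = 1L) {
  stopifnot(is.numeric(e0), length(e0) == 1L, is.numeric(emax),
            length(emax) == 1L, is.numeric(ec50), length(ec50) == 1L,
            is.numeric(hill_k), length(hill_k) == 1L)
  if (e0 < 0) abort("`e0` must be non-negative.")
  if (emax < 0) abort("`emax` must be non-negative.")
  if (ec50 <= 0) abort("`ec50` must be strictly positive.")
  if (hill_k < 1 || hill_k != round(hill_k)) {
    abort("`hill_k` must be an integer >= 1.")
  }
  structure(list(e0 = as.double(e0), emax = as.double(emax),
                 ec50 = as.double(ec50), hill_k = as.integer(hill_k)),
            class = "pd_params")
}

#' Pharmacokinetic parameters
#'
#' Parameters of the one-compartment plasma concentration equation
#' \eqn{dc/dt = -(k_1 + k_2 u(t)) c + h u(t)} with first-order clearance
#' `k1`, dose-dependent clearance coefficient `k2`, and infusion gain `h`.
#' The sign of `k2` is deliberately unrestricted: negative values model a
#' drug whose effective elimination slows as dosing increases, a regime in
#' which the concentration can grow without bound.
#'
#' @param k1 First-order clearance rate (1/time, > 0).
#' @param k2 Dose-dependent clearance coefficient (1/(time x dose), any sign).
#' @param h Infusion gain (concentration/(time x dose), > 0).
#'
#' @return An object of class `pk_params`.
#' @seealso [pk_rate()]
#' @examples
#' pk_params(k1 = 0.005, k2 = 0.0004, h = 0.001)
#' @export
pk_params <- function(k1 = 0.005, k2 = 0.0004, h = 0.001) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.numeric(k2),
            length(k2) == 1L, is.numeric(h), length(h) == 1L)
  if (k1 <= 0) abort("`k1` must be strictly positive.")
  if (h <= 0) abort("`h` must be strictly positive.")
  structure(list(k1 = as.double(k1), k2 = as.double(k2), h = as.double(h)),
            class = "pk_params")
}

#' Tumor compartment matrices
#'
#' The bilinear tumor model \eqn{dN/dt = (A + s(c) B) N} groups cell-cycle
#' phases (G0/G1/S/G2/M) into `n` compartments. `a_matrix` carries the
#' intrinsic inter-compartment flow and growth rates; `b_matrix` couples the
#' drug effect \eqn{s(c)} into those flows.
#'
#' @param a_matrix n x n numeric matrix of intrinsic rates (1/time).
#' @param b_matrix n x n numeric matrix of drug-effect coupling
#'   (1/(time x effect)).
#'
#' @return An object of class `tumor_params` with fields `a_matrix`,
#'   `b_matrix` and the compartment count `n`.
#' @examples
#' tumor_params(matrix(0.001), matrix(0.001))
#' @export
tumor_params <- function(a_matrix, b_matrix) {
  a_matrix <- as.matrix(a_matrix)
  b_matrix <- as.matrix(b_matrix)
  if (nrow(a_matrix) != ncol(a_matrix)) {
    abort("`a_matrix` must be square.")
  }
  if (!identical(dim(a_matrix), dim(b_matrix))) {
    abort("`a_matrix` and `b_matrix` must have identical dimensions.")
  }
  storage.mode(a_matrix) <- "double"
  storage.mode(b_matrix) <- "double"
  structure(list(a_matrix = a_matrix, b_matrix = b_matrix,
                 n = nrow(a_matrix)),
            class = "tumor_params")
}

#' Full model parameter bundle
#'
#' Collects tumor, pharmacokinetic and pharmacodynamic parameters plus the
#' initial cell counts and the choice of effect model into the single object
#' consumed by [simulate_chemo()] and the analysis functions.
#'
#' @param tumor A [tumor_params()] object.
#' @param pk A [pk_params()] object.
#' @param pd A [pd_params()] object.
#' @param n0 Initial cell-count vector, one strictly positive entry per
#'   compartment. Defaults to 1 per compartment (arbitrary units); the tumor
#'   equation is linear in N so trajectories scale with `n0`.
#' @param effect_model `"emax"` or `"sigmoid"`; which concentration-effect
#'   curve feeds the tumor equation.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(
#'   tumor = tumor_params(matrix(0.001), matrix(0.001)),
#'   pk = pk_params(0.005, 0.0004, 0.001),
#'   pd = pd_params(0, 100, 15)
#' )
#' @export
model_params <- function(tumor, pk, pd, n0 = NULL,
                         effect_model = c("emax", "sigmoid")) {
  stopifnot(inherits(tumor, "tumor_params"), inherits(pk, "pk_params"),
            inherits(pd, "pd_params"))
  effect_model <- match.arg(effect_model)
  n0 <- n0 %||% rep(1, tumor$n)
  n0 <- as.double(n0)
  if (length(n0) != tumor$n) {
    abort(sprintf("`n0` must have one entry per compartment (%d).", tumor$n))
  }
  if (any(n0 <= 0)) abort("All entries of `n0` must be strictly positive.")
  structure(list(tumor = tumor, pk = pk, pd = pd, n0 = n0,
                 effect_model = effect_model),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %d compartment(s), %s effect model\n",
              x$tumor$n, x$effect_model))
  cat(sprintf("  pk: k1=%g k2=%g h=%g\n", x$pk$k1, x$pk$k2, x$pk$h))
  cat(sprintf("  pd: e0=%g emax=%g ec50=%g hill_k=%d\n",
              x$pd$e0, x$pd$emax, x$pd$ec50, x$pd$hill_k))
  cat(sprintf("  n0: %s\n", paste(signif(x$n0, 4), collapse = ", ")))
  invisible(x)
}

#' Parametric dosing schedules
#'
#' Describes the drug dosage history u(t) as one of three parametric forms:
#' a constant infusion, a raised cosine
#' `u(t) = amplitude * cos(frequency * t) + offset` (periodic
#' administration), or a piecewise-constant schedule with `levels[i]` held
#' on the interval between consecutive `breakpoints`.
#'
#' Doses must be non-negative; forms whose sign is decidable at
#' construction (constant, piecewise) are validated here, and every
#' schedule is re-validated on the simulation time grid by
#' [simulate_chemo()].
#'
#' @param form One of `"constant"`, `"cosine"`, `"piecewise_constant"`.
#' @param amplitude,frequency,offset Cosine parameters; `frequency` must be
#'   positive.
#' @param level Constant dose level.
#' @param breakpoints Increasing vector of interior change times for the
#'   piecewise form.
#' @param levels Dose levels, one more than `length(breakpoints)`.
#'
#' @return An object of class `dose_schedule`.
#' @seealso [eval_dose()]
#' @examples
#' dose_schedule("cosine", amplitude = 10, frequency = 0.1, offset = 10)
#' dose_schedule("constant", level = 10)
#' @export
dose_schedule <- function(form = c("constant", "cosine", "piecewise_constant"),
                          amplitude = NULL, frequency = NULL, offset = NULL,
                          level = NULL, breakpoints = NULL, levels = NULL) {
  form <- match.arg(form)
  out <- switch(form,
    constant = {
      if (is.null(level)) abort("Constant schedule needs `level`.")
      if (level < 0) abort("Dose `level` must be non-negative.")
      list(form = form, level = as.double(level))
    },
    cosine = {
      if (is.null(amplitude) || is.null(frequency) || is.null(offset)) {
        abort("Cosine schedule needs `amplitude`, `frequency`, `offset`.")
      }
      if (frequency <= 0) abort("`frequency` must be strictly positive.")
      list(form = form, amplitude = as.double(amplitude),
           frequency = as.double(frequency), offset = as.double(offset))
    },
    piecewise_constant = {
      if (is.null(breakpoints) || is.null(levels)) {
        abort("Piecewise schedule needs `breakpoints` and `levels`.")
      }
      if (is.unsorted(breakpoints, strictly = TRUE)) {
        abort("`breakpoints` must be strictly increasing.")
      }
      if (length(levels) != length(breakpoints) + 1L) {
        abort("`levels` must have one more entry than `breakpoints`.")
      }
      if (any(levels < 0)) abort("All dose `levels` must be non-negative.")
      list(form = form, breakpoints = as.double(breakpoints),
           levels = as.double(levels))
    })
  structure(out, class = "dose_schedule")
}

#' Evaluate a dosing schedule
#'
#' @param schedule A [dose_schedule()].
#' @param t Numeric vector of times.
#' @return Numeric vector of doses u(t), same length as `t`.
#' @examples
#' sched <- dose_schedule("cosine", amplitude = 10, frequency = 0.1, offset = 10)
#' eval_dose(sched, c(0, pi / 0.1))
#' @export
eval_dose <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  switch(schedule$form,
    constant = rep(schedule$level, length(t)),
    cosine = schedule$amplitude * cos(schedule$frequency * t) +
      schedule$offset,
    piecewise_constant =
      schedule$levels[findInterval(t, schedule$breakpoints) + 1L])
}

# Reject schedules that dip below zero anywhere on the reporting grid.
validate_dose_on_grid <- function(schedule, times) {
  u <- eval_dose(schedule, times)
  if (any(u < 0)) {
    abort(sprintf(
      "Dose schedule is negative on the time grid (first at t = %g).",
      times[which(u < 0)[1L]]))
  }
  invisible(u)
}

#' Objective functional weights
#'
#' Weights of the L1-type therapy objective
#' \eqn{J = p N(T) + \int_0^T (q N(t) + b u(t)) dt}: `p` penalizes the
#' terminal tumor burden, `q` the running burden, and `b` the cumulative
#' dose (an indirect stand-in for toxicity to healthy tissue). All default
#' to 1, the reference study configuration.
#'
#' @param p Non-negative terminal weights, one per compartment.
#' @param q Non-negative running-state weights, one per compartment.
#' @param b Non-negative dose weight (single drug).
#' @param t_horizon Therapy horizon T (time units, > 0).
#'
#' @return An object of class `objective_weights`.
#' @seealso [evaluate_objective()]
#' @export
objective_weights <- function(p = 1, q = 1, b = 1, t_horizon = 500) {
  stopifnot(is.numeric(p), is.numeric(q), is.numeric(b),
            length(b) == 1L, is.numeric(t_horizon), length(t_horizon) == 1L)
  if (any(p < 0) || any(q < 0) || b < 0) {
    abort("Objective weights must be non-negative.")
  }
  if (all(p == 0) && all(q == 0) && b == 0) {
    abort("Objective weights must not all be zero.")
  }
  if (t_horizon <= 0) abort("`t_horizon` must be positive.")
  structure(list(p = as.double(p), q = as.double(q), b = as.double(b),
                 t_horizon = as.double(t_horizon)),
            class = "objective_weights")
}
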