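#' Concentration-effect function
#'
#' Evaluates the pharmacodynamic effect s(c) for a vector of concentrations.
#' With `model = "emax"` this is the hyperbolic curve
#' \eqn{E_0 + E_{max} c / (EC_{50} + c)}; with `model = "sigmoid"` the Hill
#' curve \eqn{E_0 + E_{max} c^k / (EC_{50}^k + c^k)} with `k = pd$hill_k`.
#' Both are monotone non-decreasing in c, equal `e0` at c = 0, reach
#' `e0 + emax/2` exactly at `c = ec50`, and saturate below `e0 + emax`.
#'
#' @param c Non-negative concentration(s).
#' @param pd A [pd_params()] object.
#' @param model `"emax"` or `"sigmoid"`. The two coincide when
#'   `pd$hill_k == 1`.
#' @return Effect values, same length as `c`.
#' @examples
#' drug_effect(c(0, 15, 30), pd_params(0, 100, 15))
#' @export
drug_effect <- function(c, pd, model = c("emax", "sigmoid")) {
  stopifnot(inherits(pd, "pd_params"), is.numeric(c))
  model <- match.arg(model)
  if (any(c < 0)) abort("Concentration `c` must be non-negative.")
  k <- if (model == "emax") 1L else pd$hill_k
  ck <- c^k
  pd$e0 + pd$emax * ck / (pd$ec50^k + ck)
}

# ds/dc, used by the linearization bridge.
drug_effect_deriv <- function(c, pd, model = c("emax", "sigmoid")) {
  model <- match.arg(model)
  k <- if (model == "emax") 1L else pd$hill_k
  if (c < 0) abort("Concentration `c` must be non-negative.")
  pd$emax * k * c^(k - 1) * pd$ec50^k / (pd$ec50^k + c^k)^2
}

#' Pharmacokinetic right-hand side
#'
#' Instantaneous rate of change of the plasma concentration,
#' \eqn{dc/dt = -(k_1 + k_2 u) c + h u}. Affine in `u` at fixed `c` and
#' affine in `c` at fixed `u`.
#'
#' @param c Current concentration.
#' @param u Current dose.
#' @param pk A [pk_params()] object.
#' @return dc/dt.
#' @examples
#' pk_rate(c = 1, u = 10, pk_params(0.005, 0.0004, 0.001))
#' @export
pk_rate <- function(c, u, pk) {
  stopifnot(inherits(pk, "pk_params"))
  -(pk$k1 + pk$k2 * u) * c + pk$h * u
}

#' Tumor compartment right-hand side
#'
#' Instantaneous rate of change of the compartment cell counts under the
#' bilinear model, \eqn{dN/dt = (A + s B) N} at effect level `s_val`.
#' Linear in `n_vec` at fixed `s_val`.
#'
#' @param n_vec Cell-count vector, one entry per compartment.
#' @param s_val Scalar effect value s(c).
#' @param tumor A [tumor_params()] object.
#' @return dN/dt vector.
#' @examples
#' tumor_rate(1, s_val = 50, tumor_params(matrix(0.001), matrix(0.001)))
#' @export
tumor_rate <- function(n_vec, s_val, tumor) {
  stopifnot(inherits(tumor, "tumor_params"))
  if (length(n_vec) != tumor$n) {
    abort(sprintf("`n_vec` must have length %d, got %d.",
                  tumor$n, length(n_vec)))
  }
  drop((tumor$a_matrix + s_val * tumor$b_matrix) %*% n_vec)
}
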