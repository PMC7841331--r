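#' Linear time-invariant system
#'
#' Container for the constant matrices of \eqn{dx/dt = A x + B u} and,
#' optionally, the output map \eqn{y = C x + D u}.
#'
#' @param a_matrix n x n state matrix.
#' @param b_matrix n x m input matrix.
#' @param c_matrix Optional p x n output matrix.
#' @param d_matrix Optional p x m feed-through matrix.
#' @return An object of class `linear_system`.
#' @export
linear_system <- function(a_matrix, b_matrix, c_matrix = NULL,
                          d_matrix = NULL) {
  a_matrix <- as.matrix(a_matrix)
  b_matrix <- as.matrix(b_matrix)
  n <- nrow(a_matrix)
  if (ncol(a_matrix) != n) abort("`a_matrix` must be square.")
  if (nrow(b_matrix) != n) {
    abort("`b_matrix` must have as many rows as `a_matrix`.")
  }
  if (!is.null(c_matrix)) {
    c_matrix <- as.matrix(c_matrix)
    if (ncol(c_matrix) != n) abort("`c_matrix` must have n columns.")
  }
  if (!is.null(d_matrix)) {
    d_matrix <- as.matrix(d_matrix)
    if (is.null(c_matrix) || nrow(d_matrix) != nrow(c_matrix) ||
        ncol(d_matrix) != ncol(b_matrix)) {
      abort("`d_matrix` must be p x m and accompany `c_matrix`.")
    }
  }
  structure(list(a_matrix = a_matrix, b_matrix = b_matrix,
                 c_matrix = c_matrix, d_matrix = d_matrix,
                 n = n, m = ncol(b_matrix)),
            class = "linear_system")
}

#' Kalman controllability matrix
#'
#' Horizontal concatenation \eqn{[B | AB | A^2 B | \cdots | A^{n-1} B]}.
#' An LTI system is controllable if and only if this n x (n m) matrix has
#' full row rank n.
#'
#' @param sys A [linear_system()].
#' @return The n x (n m) controllability matrix.
#' @examples
#' sys <- linear_system(matrix(c(0, 0, 1, 0), 2), matrix(c(0, 1), 2))
#' controllability_matrix(sys)
#' @export
controllability_matrix <- function(sys) {
  stopifnot(inherits(sys, "linear_system"))
  blocks <- vector("list", sys$n)
  blk <- sys$b_matrix
  for (i in seq_len(sys$n)) {
    blocks[[i]] <- blk
    blk <- sys$a_matrix %*% blk
  }
  do.call(cbind, blocks)
}

#' Kalman rank test for controllability
#'
#' Decides controllability of an LTI system from the numerical rank of the
#' controllability matrix, computed from its singular values. The default
#' rank tolerance is the standard `max(dim) * eps * largest singular value`
#' convention.
#'
#' @param sys A [linear_system()].
#' @param rank_tol Optional absolute tolerance on singular values.
#' @return An object of class `chemo_kalman`: a list with elements
#'   `controllable` (logical), `rank`, `n`, `m`, `tol` and
#'   `singular_values`. [tidy()] and [glance()] methods are provided.
#' @examples
#' dbl_int <- linear_system(matrix(c(0, 0, 1, 0), 2), matrix(c(0, 1), 2))
#' is_controllable(dbl_int)
#' @export
is_controllable <- function(sys, rank_tol = NULL) {
  e_mat <- controllability_matrix(sys)
  sv <- svd(e_mat, nu = 0, nv = 0)$d
  tol <- rank_tol %||% (max(dim(e_mat)) * .Machine$double.eps * max(sv, 0))
  rank <- sum(sv > tol)
  structure(list(controllable = rank == sys$n, rank = rank,
                 n = sys$n, m = sys$m, tol = tol, singular_values = sv),
            class = "chemo_kalman")
}

#' @export
print.chemo_kalman <- function(x, ...) {
  cat(sprintf("<chemo_kalman> rank %d of %d: %scontrollable\n",
              x$rank, x$n, if (x$controllable) "" else "NOT "))
  invisible(x)
}

#' Linearize the bilinear tumor/PK model about a reference point
#'
#' The bilinear chemotherapy model is not LTI, so the Kalman rank test does
#' not apply to it directly. This convenience builds the Jacobian
#' linearization of the coupled dynamics about a reference state
#' `(N*, c*)` and dose `u*`, producing an LTI approximation valid near that
#' point (an approximation the underlying analysis framework itself never
#' performs; results speak to the linearization only). State order is
#' `(N_1, ..., N_n, c)`, single input u:
#' \deqn{A_{lin} = \begin{pmatrix} A + s(c^*) B & s'(c^*) B N^* \\ 0 &
#'   -(k_1 + k_2 u^*) \end{pmatrix}, \quad
#'   B_{lin} = \begin{pmatrix} 0 \\ h - k_2 c^* \end{pmatrix}}
#'
#' @param params A [model_params()] bundle.
#' @param n_ref Reference cell counts (defaults to `params$n0`).
#' @param c_ref Reference concentration (default 0).
#' @param u_ref Reference dose (default 0).
#' @return A [linear_system()] with n + 1 states and one input.
#' @examples
#' sys <- linearize_chemo(study_defaults()$params, c_ref = 1, u_ref = 10)
#' is_controllable(sys)
#' @export
linearize_chemo <- function(params, n_ref = NULL, c_ref = 0, u_ref = 0) {
  stopifnot(inherits(params, "model_params"))
  n_ref <- n_ref %||% params$n0
  if (length(n_ref) != params$tumor$n) {
    abort("`n_ref` must have one entry per compartment.")
  }
  if (c_ref < 0) abort("`c_ref` must be non-negative.")
  s <- drug_effect(c_ref, params$pd, params$effect_model)
  ds <- drug_effect_deriv(c_ref, params$pd, params$effect_model)
  n <- params$tumor$n
  a_lin <- unname(rbind(
    cbind(params$tumor$a_matrix + s * params$tumor$b_matrix,
          ds * (params$tumor$b_matrix %*% cbind(n_ref))),
    c(rep(0, n), -(params$pk$k1 + params$pk$k2 * u_ref))))
  b_lin <- rbind(matrix(0, n, 1), params$pk$h - params$pk$k2 * c_ref)
  linear_system(a_lin, b_lin)
}
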