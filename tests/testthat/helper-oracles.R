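# Shared fixtures and independent oracles, built in code.

ref <- study_defaults()

one_comp_params <- function(k1 = 0.005, k2 = 0.0004, h = 0.001,
                            e0 = 0, emax = 100, ec50 = 15, hill_k = 1L,
                            A = 0.001, B = 0.001, n0 = 1,
                            effect_model = "emax") {
  model_params(
    tumor = tumor_params(matrix(A), matrix(B)),
    pk = pk_params(k1, k2, h),
    pd = pd_params(e0, emax, ec50, hill_k),
    n0 = n0, effect_model = effect_model
  )
}

# Dimension of span{columns} by classical Gram-Schmidt; independent of the
# SVD rank used by is_controllable().
gram_schmidt_rank <- function(m, tol = 1e-8) {
  basis <- list()
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    for (b in basis) v <- v - sum(v * b) * b
    nv <- sqrt(sum(v^2))
    if (nv > tol * max(1, max(abs(m)))) basis <- c(basis, list(v / nv))
  }
  length(basis)
}

# How many of the n equal-width strata of [lo, hi] each sample falls in.
stratum_counts <- function(x, lo, hi, n) {
  idx <- pmin(floor((x - lo) / (hi - lo) * n), n - 1)
  tabulate(idx + 1L, nbins = n)
}

# Trapezoid rule written out longhand, independent of pracma.
trapz_oracle <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
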