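#' Tidy a Kalman controllability test
#'
#' One row per singular value of the controllability matrix.
#'
#' @param x A `chemo_kalman` object from [is_controllable()].
#' @param ... Unused.
#' @return A tibble with columns `index`, `singular_value`,
#'   `above_tolerance`.
#' @export
tidy.chemo_kalman <- function(x, ...) {
  tibble(index = seq_along(x$singular_values),
         singular_value = x$singular_values,
         above_tolerance = x$singular_values > x$tol)
}

#' Glance at a Kalman controllability test
#'
#' @param x A `chemo_kalman` object.
#' @param ... Unused.
#' @return A one-row tibble with `controllable`, `rank`, `n`, `m`, `tol`.
#' @export
glance.chemo_kalman <- function(x, ...) {
  tibble(controllable = x$controllable, rank = x$rank, n = x$n, m = x$m,
         tol = x$tol)
}

#' Glance at a simulated trajectory
#'
#' @param x A `chemo_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble with the horizon, compartment count, final
#'   concentration, final total cell count and cumulative dose.
#' @export
glance.chemo_trajectory <- function(x, ...) {
  n_cols <- grep("^N_", names(x), value = TRUE)
  tibble(
    t_end = max(x$time),
    n_compartments = length(n_cols),
    final_concentration = x$c[nrow(x)],
    final_cells = sum(as_tibble(x)[nrow(x), n_cols]),
    total_dose = pracma::trapz(x$time, x$u)
  )
}

#' Tidy a parameter sensitivity ranking
#'
#' @param x A `chemo_ranking`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `score`, `rank`.
#' @export
tidy.chemo_ranking <- function(x, ...) {
  as_tibble(x)[c("parameter", "score", "rank")]
}

#' Glance at a sensitivity envelope
#'
#' @param x A `chemo_envelope`.
#' @param ... Unused.
#' @return A one-row tibble with sample counts, failures, the output
#'   variable and summary band widths.
#' @export
glance.chemo_envelope <- function(x, ...) {
  width <- x$max - x$min
  tibble(
    n_samples = attr(x, "n_samples"),
    n_failed = attr(x, "n_failed"),
    output = attr(x, "output"),
    mean_width = mean(width),
    max_width = max(width)
  )
}
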