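#' Serialize a parameter bundle to JSON
#'
#' Writes a [model_params()] bundle — optionally together with a dosing
#' schedule and objective weights — to a JSON configuration document whose
#' keys mirror the field names. Numbers are emitted at full precision so
#' that [params_from_json()] round-trips exactly.
#'
#' @param params A [model_params()] object.
#' @param schedule Optional [dose_schedule()].
#' @param weights Optional [objective_weights()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @examples
#' cfg <- params_to_json(study_defaults()$params)
#' identical(params_from_json(cfg)$params, study_defaults()$params)
#' @export
params_to_json <- function(params, schedule = NULL, weights = NULL,
                           path = NULL) {
  stopifnot(inherits(params, "model_params"))
  doc <- list(
    tumor = list(a_matrix = params$tumor$a_matrix,
                 b_matrix = params$tumor$b_matrix),
    pk = unclass(params$pk),
    pd = unclass(params$pd),
    n0 = params$n0,
    effect_model = params$effect_model
  )
  if (!is.null(schedule)) doc$schedule <- unclass(schedule)
  if (!is.null(weights)) doc$weights <- unclass(weights)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Deserialize a parameter bundle from JSON
#'
#' Inverse of [params_to_json()]. Reconstructs the bundle through the
#' validating constructors, so an edited configuration that violates an
#' invariant is rejected with the same messages as direct construction.
#'
#' @param json A JSON string or path to a JSON file.
#' @return A list with elements `params` ([model_params()]) and, when
#'   present in the document, `schedule` and `weights`.
#' @export
params_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  params <- model_params(
    tumor = tumor_params(doc$tumor$a_matrix, doc$tumor$b_matrix),
    pk = pk_params(doc$pk$k1, doc$pk$k2, doc$pk$h),
    pd = pd_params(doc$pd$e0, doc$pd$emax, doc$pd$ec50, doc$pd$hill_k),
    n0 = doc$n0,
    effect_model = doc$effect_model
  )
  out <- list(params = params)
  if (!is.null(doc$schedule)) {
    s <- doc$schedule
    out$schedule <- dose_schedule(
      form = s$form, amplitude = s$amplitude, frequency = s$frequency,
      offset = s$offset, level = s$level, breakpoints = s$breakpoints,
      levels = s$levels)
  }
  if (!is.null(doc$weights)) {
    w <- doc$weights
    out$weights <- objective_weights(w$p, w$q, w$b, w$t_horizon)
  }
  out
}

#' Read a linear system from a JSON document
#'
#' Matrices are stored as nested row-major lists under keys `a_matrix`,
#' `b_matrix` and optionally `c_matrix`, `d_matrix`.
#'
#' @param json A JSON string or file path.
#' @return A [linear_system()].
#' @export
linear_system_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  linear_system(doc$a_matrix, doc$b_matrix,
                c_matrix = doc$c_matrix, d_matrix = doc$d_matrix)
}
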