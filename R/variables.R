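#' Define a clinical variable
#'
#' A variable specification describes one measured quantity in the event
#' stream: its physiologic range (used to normalise values before the
#' sinusoidal value embedding and to clamp out-of-range readings) and,
#' optionally, its clinical normal range (used by the five-level value
#' binning of the interpretability module).
#'
#' @param variable_id Short string key, unique within a dictionary.
#' @param kind `"real"` for numeric measurements, `"boolean"` for
#'   present/absent events (e.g. diagnosis codes); boolean events carry
#'   value 1 and have no range.
#' @param v_min,v_max Physiologic minimum/maximum, in the variable's own
#'   units. Required for `kind = "real"`.
#' @param normal_low,normal_high Clinical normal range, or `NA` if no
#'   normal range is defined. Both must lie inside `[v_min, v_max]`.
#' @param display_name Human-readable name.
#' @return A list of class `pave_variable`.
#' @examples
#' variable_spec("heart_rate", "real", 20, 220, 60, 100, "Heart rate")
#' @export
variable_spec <- function(variable_id, kind = c("real", "boolean"),
                          v_min = NA_real_, v_max = NA_real_,
                          normal_low = NA_real_, normal_high = NA_real_,
                          display_name = variable_id) {
  kind <- match.arg(kind)
  if (!is.character(variable_id) || length(variable_id) != 1L || !nzchar(variable_id))
    stopf("variable_id must be a non-empty string")
  if (kind == "real") {
    if (!is.finite(v_min) || !is.finite(v_max) || v_min >= v_max)
      stopf("variable '%s': need finite v_min < v_max for a real variable", variable_id)
    if (!is.na(normal_low) != !is.na(normal_high))
      stopf("variable '%s': normal_low and normal_high must be given together", variable_id)
    if (!is.na(normal_low)) {
      if (normal_low >= normal_high)
        stopf("variable '%s': normal_low must be < normal_high", variable_id)
      if (normal_low < v_min || normal_high > v_max)
        stopf("variable '%s': normal range must lie within [v_min, v_max]", variable_id)
    }
  } else {
    v_min <- NA_real_; v_max <- NA_real_
    normal_low <- NA_real_; normal_high <- NA_real_
  }
  structure(
    list(variable_id = variable_id, kind = kind,
         v_min = as.numeric(v_min), v_max = as.numeric(v_max),
         normal_low = as.numeric(normal_low), normal_high = as.numeric(normal_high),
         display_name = display_name),
    class = "pave_variable")
}

as_variable_dict <- function(specs) {
  ids <- vapply(specs, `[[`, "", "variable_id")
  if (anyDuplicated(ids)) stopf("duplicate variable_id in dictionary")
  names(specs) <- ids
  specs
}

#' Read or write a variable dictionary (YAML)
#'
#' The dictionary file holds one entry per variable with the fields of
#' [variable_spec()]. Two example dictionaries ship with the package
#' (see [default_variable_dict()]).
#'
#' @param path Path to a YAML file.
#' @return `read_variable_dict()` returns a named list of
#'   `pave_variable` specs keyed by `variable_id`.
#' @export
read_variable_dict <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(v) {
    variable_spec(variable_id = v$variable_id, kind = v$kind %||% "real",
                  v_min = v$v_min %||% NA_real_, v_max = v$v_max %||% NA_real_,
                  normal_low = v$normal_low %||% NA_real_,
                  normal_high = v$normal_high %||% NA_real_,
                  display_name = v$display_name %||% v$variable_id)
  })
  as_variable_dict(specs)
}

#' @rdname read_variable_dict
#' @param variables Named list of `pave_variable` specs.
#' @export
write_variable_dict <- function(variables, path) {
  out <- lapply(unname(variables), function(v) {
    v <- unclass(v)
    v[!vapply(v, function(x) is.na(x) && is.numeric(x), FALSE)]
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Built-in variable dictionaries
#'
#' `default_variable_dict()` returns the eight routinely collected vital
#' signs used for mortality-style risk prediction (heart rate,
#' respiratory rate, temperature, systolic/diastolic/mean blood
#' pressure, SpO2, glucose). `sepsis_variable_dict()` adds the
#' laboratory variables needed by the SIRS sepsis criteria (WBC, PaCO2,
#' band neutrophils). Ranges are conventional adult reference values.
#'
#' @return Named list of `pave_variable` specs.
#' @export
default_variable_dict <- function() {
  read_variable_dict(system.file("extdata", "variables_vitals.yaml",
                                 package = "pave", mustWork = TRUE))
}

#' @rdname default_variable_dict
#' @export
sepsis_variable_dict <- function() {
  read_variable_dict(system.file("extdata", "variables_sepsis.yaml",
                                 package = "pave", mustWork = TRUE))
}
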