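# Domain types and plumbing for patient event streams.
#
# An event stream is a data.frame with one row per observed measurement:
#   variable_id (chr), value (dbl), time (dbl, hours on a patient-local
#   clock, larger = later), collection_id (int, groups simultaneous
#   measurements). Only observed measurements are represented; there is
#   no missing-value placeholder anywhere in the pipeline.

PAVE_GENDERS <- c("male", "female", "other")
PAVE_AGE_GROUPS <- c("0-9", "10-19", "20-29", "30-39", "40-49",
                     "50-59", "60-69", "70-79", "80-89", "90+")

#' Decade age group of an age in years
#'
#' Ages are binned into decades `"0-9"` ... `"80-89"` with an open-ended
#' `"90+"` bin, the grouping used for demographic embedding and for
#' case-control matching.
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of age-group labels.
#' @examples
#' age_group_of(c(4, 67, 95))
#' @export
age_group_of <- function(age) {
  if (any(!is.finite(age) | age < 0)) stopf("ages must be finite and non-negative")
  idx <- pmin(age %/% 10, 9) + 1L
  PAVE_AGE_GROUPS[idx]
}

empty_events <- function() {
  data.frame(variable_id = character(), value = numeric(),
             time = numeric(), collection_id = integer(),
             stringsAsFactors = FALSE)
}

sort_events <- function(events) {
  # ascending time; ties broken by (collection_id, variable_id) so that
  # serialisation is reproducible (the model itself is order-invariant)
  events[order(events$time, events$collection_id, events$variable_id), ,
         drop = FALSE]
}

#' Construct a patient record
#'
#' @param patient_id String identifier.
#' @param gender One of `"male"`, `"female"`, `"other"`.
#' @param age_group One of the decade bins `"0-9"` ... `"90+"`
#'   (see [age_group_of()]).
#' @param events Data frame with columns `variable_id`, `value`, `time`
#'   (hours, patient-local clock), `collection_id`. Sorted on
#'   construction.
#' @param label Binary outcome, 0 or 1.
#' @param anchor_time Clinical reference point on the patient clock:
#'   onset/death time for cases, the matched index time for controls.
#' @return A list of class `pave_patient`.
#' @export
new_patient <- function(patient_id, gender, age_group, events = empty_events(),
                        label = 0L, anchor_time = 0) {
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stopf("patient_id must be a single string")
  if (!gender %in% PAVE_GENDERS)
    stopf("patient '%s': unknown gender '%s'", patient_id, gender)
  if (!age_group %in% PAVE_AGE_GROUPS)
    stopf("patient '%s': unknown age_group '%s'", patient_id, age_group)
  if (!all(label %in% c(0, 1)) || length(label) != 1L)
    stopf("patient '%s': label must be 0 or 1", patient_id)
  if (!is.finite(anchor_time))
    stopf("patient '%s': anchor_time must be finite", patient_id)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  need <- c("variable_id", "value", "time", "collection_id")
  if (!all(need %in% names(events)))
    stopf("patient '%s': events need columns %s", patient_id,
          paste(need, collapse = ", "))
  events <- events[need]
  if (nrow(events)) {
    if (any(!is.finite(events$time)))
      stopf("patient '%s': event times must be finite", patient_id)
    if (any(!is.finite(events$value)))
      stopf("patient '%s': event values must be finite", patient_id)
    events$collection_id <- as.integer(events$collection_id)
    events <- sort_events(events)
  }
  rownames(events) <- NULL
  structure(
    list(patient_id = patient_id,
         demographics = list(gender = gender, age_group = age_group),
         events = events, label = as.integer(label),
         anchor_time = as.numeric(anchor_time)),
    class = "pave_patient")
}

#' Construct a cohort
#'
#' A cohort bundles patients with the variable dictionary that resolves
#' their event streams, plus the observation-window geometry used for
#' model input extraction.
#'
#' @param patients List of [new_patient()] records.
#' @param variables Named list of [variable_spec()]s; every
#'   `variable_id` appearing in any event stream must resolve here.
#' @param observation_hours Length of the history window the model may
#'   see (hours).
#' @param holdoff_hours Gap between the last observable data and the
#'   anchor time (hours); data inside it are excluded.
#' @return A list of class `pave_cohort`.
#' @export
new_cohort <- function(patients, variables, observation_hours = 48,
                       holdoff_hours = 0) {
  stopifnot(is.list(patients), is.list(variables))
  known <- names(variables)
  for (p in patients) {
    if (!inherits(p, "pave_patient")) stopf("patients must be pave_patient records")
    bad <- setdiff(unique(p$events$variable_id), known)
    if (length(bad))
      stopf("patient '%s': unknown variable_id(s): %s", p$patient_id,
            paste(bad, collapse = ", "))
  }
  structure(
    list(patients = patients, variables = variables,
         observation_hours = as.numeric(observation_hours),
         holdoff_hours = as.numeric(holdoff_hours)),
    class = "pave_cohort")
}

#' @export
print.pave_cohort <- function(x, ...) {
  labs <- vapply(x$patients, `[[`, 0L, "label")
  nev <- sum(vapply(x$patients, function(p) nrow(p$events), 0L))
  cat(sprintf(
    "<pave_cohort> %d patients (%d cases / %d controls), %d events, %d variables\n",
    length(x$patients), sum(labs == 1L), sum(labs == 0L), nev,
    length(x$variables)))
  cat(sprintf("  observation window %g h, hold-off %g h\n",
              x$observation_hours, x$holdoff_hours))
  invisible(x)
}

#' @export
print.pave_patient <- function(x, ...) {
  cat(sprintf("<pave_patient> %s (%s, %s), label %d, %d events, anchor %g h\n",
              x$patient_id, x$demographics$gender, x$demographics$age_group,
              x$label, nrow(x$events), x$anchor_time))
  invisible(x)
}

patient_to_json <- function(p) {
  ev <- p$events
  events <- if (nrow(ev)) {
    lapply(seq_len(nrow(ev)), function(i)
      list(ev$variable_id[i], ev$value[i], ev$time[i], ev$collection_id[i]))
  } else list()
  jsonlite::toJSON(
    list(patient_id = p$patient_id, label = p$label,
         anchor_time = p$anchor_time,
         demographics = p$demographics, events = events),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read and write event-stream cohort files
#'
#' Cohorts are serialised as UTF-8 line-delimited JSON, one patient per
#' line, with fields `patient_id`, `label`, `anchor_time`,
#' `demographics` (object with `gender`, `age_group`) and `events` (an
#' array of `[variable_id, value, time, collection_id]` tuples; times in
#' hours as decimal floats). Writing then reading reproduces every field.
#'
#' @param path Path to the `.jsonl` event-stream file.
#' @param variables_path Path to the YAML variable dictionary, or
#'   alternatively pass a dictionary via `variables`.
#' @param variables Named list of [variable_spec()]s (overrides
#'   `variables_path`).
#' @param observation_hours,holdoff_hours Window geometry recorded on
#'   the returned cohort.
#' @return `read_cohort()` returns a [new_cohort()]; `write_cohort()`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path, variables_path = NULL, variables = NULL,
                        observation_hours = 48, holdoff_hours = 0) {
  if (is.null(variables)) {
    if (is.null(variables_path)) stopf("supply variables_path or variables")
    variables <- read_variable_dict(variables_path)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  patients <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stopf("line %d: malformed record (%s)", i, conditionMessage(e)))
    ev <- rec$events %||% list()
    n <- length(ev)
    events <- if (n) {
      ok <- vapply(ev, function(e) length(e) == 4L, FALSE)
      if (!all(ok)) stopf("line %d: events must be 4-tuples", i)
      df <- data.frame(
        variable_id = vapply(ev, function(e) as.character(e[[1]]), ""),
        value = vapply(ev, function(e) suppressWarnings(as.numeric(e[[2]])), 0),
        time = vapply(ev, function(e) suppressWarnings(as.numeric(e[[3]])), 0),
        collection_id = vapply(ev, function(e) suppressWarnings(as.integer(e[[4]])), 0L),
        stringsAsFactors = FALSE)
      if (any(!is.finite(df$time)) || any(!is.finite(df$value)))
        stopf("line %d: non-finite event value or time", i)
      df
    } else empty_events()
    patients[[i]] <- tryCatch(
      new_patient(as.character(rec$patient_id), rec$demographics$gender,
                  rec$demographics$age_group, events,
                  rec$label, rec$anchor_time),
      error = function(e) stopf("line %d: %s", i, conditionMessage(e)))
  }
  new_cohort(patients, variables, observation_hours, holdoff_hours)
}

#' @rdname read_cohort
#' @param cohort A [new_cohort()] object.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "pave_cohort"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in cohort$patients) writeLines(patient_to_json(p), con)
  invisible(path)
}

#' Restrict a patient to the observation window
#'
#' Keeps exactly the events whose time lies in the half-open interval
#' `[anchor - holdoff - observation, anchor - holdoff)` — closed at the
#' older edge — so that data inside the hold-off prediction window are
#' excluded. Label, demographics and anchor are unchanged. An empty
#' window is returned as a patient with zero events; exclusion is the
#' caller's decision (see [window_cohort()]).
#'
#' @param patient A [new_patient()] record with `anchor_time` set.
#' @param observation_hours,holdoff_hours Window geometry in hours.
#' @return The windowed patient.
#' @examples
#' p <- new_patient("p1", "male", "60-69",
#'   data.frame(variable_id = "heart_rate", value = 80,
#'              time = c(-60, -40, -5, -2), collection_id = 1:4),
#'   label = 1, anchor_time = 0)
#' nrow(extract_observation_window(p, 48, 10)$events)  # only t = -40 kept
#' @export
extract_observation_window <- function(patient, observation_hours = 48,
                                       holdoff_hours = 0) {
  stopifnot(inherits(patient, "pave_patient"))
  end <- patient$anchor_time - holdoff_hours
  start <- end - observation_hours
  keep <- patient$events$time >= start & patient$events$time < end
  patient$events <- patient$events[keep, , drop = FALSE]
  rownames(patient$events) <- NULL
  patient
}

#' Window every patient in a cohort
#'
#' Applies [extract_observation_window()] with the cohort's stored
#' geometry and drops patients whose window contains no events,
#' reporting how many were excluded.
#'
#' @param cohort A [new_cohort()].
#' @param quiet Suppress the exclusion message.
#' @return The windowed cohort.
#' @export
window_cohort <- function(cohort, quiet = FALSE) {
  stopifnot(inherits(cohort, "pave_cohort"))
  windowed <- lapply(cohort$patients, extract_observation_window,
                     observation_hours = cohort$observation_hours,
                     holdoff_hours = cohort$holdoff_hours)
  nonempty <- vapply(windowed, function(p) nrow(p$events) > 0L, FALSE)
  if (!quiet && any(!nonempty))
    message(sprintf("window_cohort: excluded %d patient(s) with empty windows",
                    sum(!nonempty)))
  cohort$patients <- windowed[nonempty]
  cohort
}

#' Recency time deltas of a windowed event stream
#'
#' For each event, the lag in hours behind the most recent event in the
#' window: `t_i = max(time) - time_i`. All deltas are non-negative and
#' the latest event has delta 0. This recency encoding is what the time
#' embedding consumes; an alternative previous-event mode (`mode =
#' "previous"`, gap to the preceding event) is available for sensitivity
#' analyses.
#'
#' @param patient A [new_patient()] record with at least one event.
#' @param mode `"recency"` (default) or `"previous"`.
#' @return Numeric vector of deltas, one per event (in event order).
#' @examples
#' p <- new_patient("p1", "male", "60-69",
#'   data.frame(variable_id = "heart_rate", value = 80,
#'              time = c(0, 2, 5), collection_id = 1:3))
#' compute_time_deltas(p)  # 5 3 0
#' @export
compute_time_deltas <- function(patient, mode = c("recency", "previous")) {
  mode <- match.arg(mode)
  times <- patient$events$time
  if (!length(times)) stopf("no events in window")
  if (mode == "recency") max(times) - times
  else c(0, diff(times))
}

#' Age/gender matched control selection
#'
#' For each case patient, draws `ratio` controls with the identical
#' (age group, gender) stratum from a pool of label-0 patients, sampling
#' without replacement across the whole cohort with a seeded generator.
#' Each selected control is assigned its case's `anchor_time` as index
#' time. Cases whose stratum has fewer than `ratio` unused pool patients
#' are dropped with a warning.
#'
#' @param cases List of case patients (label 1).
#' @param pool List of candidate controls (label 0).
#' @param ratio Controls per case (default 3).
#' @param seed Integer seed for the selection.
#' @param variables Variable dictionary for the returned cohort.
#' @param observation_hours,holdoff_hours Window geometry for the
#'   returned cohort.
#' @return A [new_cohort()] with retained cases followed by their
#'   matched controls.
#' @export
match_controls <- function(cases, pool, ratio = 3L, seed = 1L, variables,
                           observation_hours = 48, holdoff_hours = 0) {
  if (!is.numeric(ratio) || ratio < 1) stopf("ratio must be >= 1")
  ratio <- as.integer(ratio)
  if (any(vapply(pool, `[[`, 0L, "label") != 0L))
    stopf("pool must contain only label-0 patients")
  stratum <- function(p) paste(p$demographics$age_group, p$demographics$gender,
                               sep = "|")
  pool_strata <- vapply(pool, stratum, "")
  used <- logical(length(pool))
  out <- list()
  dropped <- character()
  with_seed(seed, {
    for (cs in cases) {
      eligible <- which(pool_strata == stratum(cs) & !used)
      if (length(eligible) < ratio) {
        dropped <- c(dropped, cs$patient_id)
        next
      }
      pick <- if (length(eligible) == 1L) eligible
              else sample(eligible, ratio)
      used[pick] <- TRUE
      ctrls <- lapply(pool[pick], function(p) {
        p$anchor_time <- cs$anchor_time
        p
      })
      out <- c(out, list(cs), ctrls)
    }
  })
  if (length(dropped))
    warnf("match_controls: dropped %d case(s) with insufficient matches: %s",
          length(dropped), paste(dropped, collapse = ", "))
  new_cohort(out, variables, observation_hours, holdoff_hours)
}
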