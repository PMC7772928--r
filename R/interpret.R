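# Pattern-level interpretability: per-pair contribution scores from the
# two attention stages, five-level value binning against clinical normal
# ranges, cohort-level pattern ranking, and per-patient explanation
# export.

BIN_LEVELS <- c("very_low", "low", "normal", "high", "very_high")

#' Contribution matrix of a forward trace
#'
#' The contribution of the ordered event pair `(i, j)` is
#' `C_ij = gamma_i * alpha_ij`: the pattern weight of event `i` times
#' the self-attention weight it places on event `j`. Because each row of
#' `alpha` sums to 1 and `gamma` sums to 1, the whole matrix carries
#' unit mass, so entries are directly interpretable as contribution
#' rates.
#'
#' @param trace A `pave_trace` from [pave_forward()].
#' @return List of class `pave_contrib` with `C` (`n x n`, non-negative,
#'   summing to 1) and `events` (the trace's event table indexing the
#'   rows).
#' @export
contribution_matrix <- function(trace) {
  stopifnot(inherits(trace, "pave_trace"))
  C <- trace$gamma * trace$alpha
  structure(list(C = C, events = trace$events, y = trace$y,
                 patient_id = trace$patient_id),
            class = "pave_contrib")
}

#' Out-of-range side medians for five-level binning
#'
#' For each variable, collects all observed values below the normal
#' range and all above it — by default over case patients only — and
#' returns the median of each side. These medians split the low and high
#' ranges into low/very-low and high/very-high.
#'
#' @param cohort A (typically windowed) [new_cohort()].
#' @param cases_only Use case patients only (default) or the whole
#'   cohort.
#' @return Named list per variable: `list(low = median or NA, high =
#'   median or NA)`.
#' @export
compute_side_medians <- function(cohort, cases_only = TRUE) {
  stopifnot(inherits(cohort, "pave_cohort"))
  pats <- cohort$patients
  if (cases_only) pats <- Filter(function(p) p$label == 1L, pats)
  vals <- list()
  for (p in pats) {
    sp <- split(p$events$value, p$events$variable_id)
    for (id in names(sp)) vals[[id]] <- c(vals[[id]], sp[[id]])
  }
  out <- lapply(names(cohort$variables), function(id) {
    v <- cohort$variables[[id]]
    x <- vals[[id]]
    if (v$kind != "real" || is.na(v$normal_low))
      return(list(low = NA_real_, high = NA_real_))
    list(low = if (any(x < v$normal_low)) stats::median(x[x < v$normal_low])
               else NA_real_,
         high = if (any(x > v$normal_high)) stats::median(x[x > v$normal_high])
                else NA_real_)
  })
  names(out) <- names(cohort$variables)
  out
}

#' Five-level value binning
#'
#' Maps a measurement to one of `very_low`, `low`, `normal`, `high`,
#' `very_high`: values inside the variable's normal range are `normal`;
#' values above it are split at the median of the observed
#' above-normal values (`high` at or below the median — ties go to the
#' inner bin — `very_high` above it), and the low side symmetrically.
#' When a side median is unavailable (no out-of-range observations on
#' that side) the whole side maps to the inner bin.
#'
#' @param value Numeric value.
#' @param spec The variable's [variable_spec()]; must carry a normal
#'   range.
#' @param side_median_high,side_median_low Side medians, e.g. from
#'   [compute_side_medians()].
#' @return One of the five level strings.
#' @examples
#' sp <- variable_spec("temperature", "real", 32, 42.5, 36, 38)
#' bin_value(39.4, sp, side_median_high = 39.0)  # "very_high"
#' @export
bin_value <- function(value, spec, side_median_high = NA_real_,
                      side_median_low = NA_real_) {
  if (is.na(spec$normal_low) || is.na(spec$normal_high))
    stopf("variable '%s' has no normal range; cannot bin", spec$variable_id)
  vapply(value, function(v) {
    if (v < spec$normal_low) {
      if (!is.na(side_median_low) && v < side_median_low) "very_low" else "low"
    } else if (v > spec$normal_high) {
      if (!is.na(side_median_high) && v > side_median_high) "very_high" else "high"
    } else "normal"
  }, "")
}

# binned level of every event in a trace's event table
bin_events <- function(events, variables, medians) {
  vapply(seq_len(nrow(events)), function(i) {
    id <- events$variable_id[i]
    sp <- variables[[id]]
    if (sp$kind != "real" || is.na(sp$normal_low)) return("observed")
    m <- medians[[id]]
    bin_value(events$value[i], sp, m$high, m$low)
  }, "")
}

pattern_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = " || ")
}

#' Cohort-level pattern ranking
#'
#' For every case patient, computes the contribution matrix, labels each
#' event with its binned level, and accumulates contribution mass per
#' unordered `(variable level, variable level)` pair key: the key
#' `(a, b)` receives `C_ij + C_ji` for every distinct pair of events
#' `i != j` mapping to it. Self pairs (`i == j`) are kept under a
#' separate `(event, itself)` key and excluded from the two-event
#' ranking. Each patient's masses are percentages of that patient's unit
#' total; keys absent for a patient count as 0, and the per-key average
#' over case patients (AVG-CR, in percent) ranks the patterns.
#'
#' @param cohort A [new_cohort()] containing case patients; windowed
#'   internally with its stored geometry.
#' @param model A trained [pave_model()].
#' @param top_k Number of top patterns to return (default 10).
#' @param medians Optional precomputed [compute_side_medians()] result.
#' @param cases_only Compute side medians from case patients only
#'   (default).
#' @return List of class `pave_ranking`: `top` (data frame `event_1`,
#'   `event_2`, `avg_cr` for the `top_k` two-event patterns), `all`
#'   (every key including self pairs, with an `is_self` flag), and
#'   `n_cases`.
#' @export
rank_patterns <- function(cohort, model, top_k = 10L, medians = NULL,
                          cases_only = TRUE) {
  wc <- window_cohort(cohort, quiet = TRUE)
  cases <- Filter(function(p) p$label == 1L, wc$patients)
  if (!length(cases)) stopf("rank_patterns: no case patients in cohort")
  if (is.null(medians)) medians <- compute_side_medians(wc, cases_only)
  acc <- new.env(parent = emptyenv())
  selfkey <- new.env(parent = emptyenv())
  for (p in cases) {
    tr <- pave_forward(p, model)
    C <- tr$gamma * tr$alpha
    lev <- bin_events(tr$events, wc$variables, medians)
    tag <- paste(tr$events$variable_id, lev)
    n <- nrow(C)
    # unordered aggregation: the key (a, b) receives C_ij + C_ji
    keys <- paste(tag, "|| (itself)")
    mass <- diag(C)
    for (k in unique(keys)) selfkey[[k]] <- TRUE
    if (n > 1L) {
      ut <- upper.tri(C)
      iu <- which(ut, arr.ind = TRUE)
      a <- tag[iu[, 1L]]; b <- tag[iu[, 2L]]
      keys <- c(keys, paste(pmin(a, b), pmax(a, b), sep = " || "))
      mass <- c(mass, C[ut] + t(C)[ut])
    }
    per_key <- tapply(100 * mass, keys, sum)
    for (k in names(per_key)) acc[[k]] <- (acc[[k]] %||% 0) + per_key[[k]]
  }
  keys <- ls(acc)
  avg <- vapply(keys, function(k) acc[[k]] / length(cases), 0)
  is_self <- vapply(keys, function(k) isTRUE(selfkey[[k]]), FALSE)
  ord <- order(avg, decreasing = TRUE)
  all_df <- data.frame(pattern = keys[ord], avg_cr = avg[ord],
                       is_self = is_self[ord], row.names = NULL,
                       stringsAsFactors = FALSE)
  two <- all_df[!all_df$is_self, , drop = FALSE]
  halves <- strsplit(two$pattern, " \\|\\| ")
  top <- utils::head(data.frame(
    event_1 = vapply(halves, `[[`, "", 1L),
    event_2 = vapply(halves, `[[`, "", 2L),
    avg_cr = two$avg_cr, row.names = NULL, stringsAsFactors = FALSE), top_k)
  structure(list(top = top, all = all_df, n_cases = length(cases)),
            class = "pave_ranking")
}

#' @export
print.pave_ranking <- function(x, ...) {
  cat(sprintf("<pave_ranking> top patterns over %d case patients\n", x$n_cases))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Per-patient explanation
#'
#' Runs a forward pass, bins the patient's values, and reports the risk
#' together with every event pair whose contribution `C_ij` reaches
#' `threshold` (lower thresholds yield supersets; at threshold 0 the
#' reported contributions sum to 1).
#'
#' @param patient A (windowed or windowable) [new_patient()].
#' @param model A trained [pave_model()].
#' @param threshold Minimum contribution to report.
#' @param medians Optional [compute_side_medians()] result for binning;
#'   without it the patient's own out-of-range values define the side
#'   medians.
#' @return List of class `pave_explanation`: `patient_id`, `y`, and a
#'   `patterns` data frame (variables, binned levels, times,
#'   contribution, descending).
#' @export
explain_patient <- function(patient, model, threshold = 0.01, medians = NULL) {
  tr <- pave_forward(patient, model)
  if (is.null(medians)) {
    tmp <- new_cohort(list(`if`(patient$label == 1L, patient, {
      p <- patient; p$label <- 1L; p
    })), model$variables, Inf, 0)
    medians <- compute_side_medians(tmp)
  }
  C <- tr$gamma * tr$alpha
  lev <- bin_events(tr$events, model$variables, medians)
  idx <- which(C >= threshold, arr.ind = TRUE)
  pat <- if (nrow(idx)) {
    data.frame(
      variable_1 = tr$events$variable_id[idx[, 1L]],
      level_1 = lev[idx[, 1L]],
      time_1 = tr$events$time[idx[, 1L]],
      variable_2 = tr$events$variable_id[idx[, 2L]],
      level_2 = lev[idx[, 2L]],
      time_2 = tr$events$time[idx[, 2L]],
      contribution = C[idx], stringsAsFactors = FALSE)
  } else data.frame(variable_1 = character(), level_1 = character(),
                    time_1 = numeric(), variable_2 = character(),
                    level_2 = character(), time_2 = numeric(),
                    contribution = numeric())
  pat <- pat[order(pat$contribution, decreasing = TRUE), , drop = FALSE]
  rownames(pat) <- NULL
  structure(list(patient_id = tr$patient_id, y = tr$y, threshold = threshold,
                 patterns = pat),
            class = "pave_explanation")
}

#' Export explanations and rankings
#'
#' `write_explanation()` serialises a [explain_patient()] record to JSON;
#' `write_ranking()` writes the top patterns of a [rank_patterns()]
#' result as a tab-delimited table with columns `event_1`, `event_2`,
#' `avg_cr`.
#'
#' @param x The explanation or ranking object.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_explanation <- function(x, path) {
  stopifnot(inherits(x, "pave_explanation"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_explanation
#' @export
write_ranking <- function(x, path) {
  stopifnot(inherits(x, "pave_ranking"))
  utils::write.table(x$top, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
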