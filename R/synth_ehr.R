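# Synthetic matched case-control cohort simulator.
#
# The generator emulates the shape of ICU vital-sign streams: irregular
# collection times (exponential inter-arrivals), per-collection
# measurements with heavy missingness, values that normally sit inside
# each variable's clinical normal range, and occasional out-of-range
# excursions. Risk is carried by a planted TWO-EVENT pattern: case
# patients receive simultaneous out-of-range excursions of both pattern
# variables in the same collections, while any single pattern variable
# excursion occurs at the same rate in cases and controls — so each
# event alone carries no signal and only the co-occurrence separates the
# classes.

#' Planted two-event risk pattern
#'
#' @param variable_a,variable_b Variable ids of the interacting pair.
#' @param level_a,level_b Target binned levels; the side (`high`/
#'   `very_high` vs `low`/`very_low`) determines the excursion
#'   direction, and planted excursions are drawn in the outer (very)
#'   part of the side so that they bin as `very_*` once the side median
#'   is estimated.
#' @param joint_risk Probability that a case patient carries the joint
#'   co-occurring excursions; must exceed `marginal_risk`.
#' @param marginal_risk Probability that a patient *not* carrying the
#'   joint pattern carries a lone excursion episode of `variable_a`
#'   (at most one of the two variables per patient). Because this rate
#'   is identical in cases and controls, either variable alone at its
#'   target level confers only marginal information; the sharp risk
#'   increase is tied to the co-occurrence.
#' @param marginal_risk_b Lone-episode probability for `variable_b`
#'   (default the same as `marginal_risk`); an asymmetric pair can be
#'   specified when one member of the pair should be a more common lone
#'   finding than the other.
#' @return A list of class `pave_pattern`.
#' @export
planted_pattern <- function(variable_a = "temperature", level_a = "very_high",
                            variable_b = "heart_rate", level_b = "very_high",
                            joint_risk = 0.88, marginal_risk = 0.3,
                            marginal_risk_b = marginal_risk) {
  level_side(level_a); level_side(level_b)
  if (!(joint_risk > 0 && joint_risk < 1) ||
      !(marginal_risk > 0 && marginal_risk < 1) ||
      !(marginal_risk_b > 0 && marginal_risk_b < 1))
    stopf("joint_risk and marginal risks must lie in (0, 1)")
  if (joint_risk <= marginal_risk)
    stopf("joint_risk must exceed marginal_risk")
  if (marginal_risk + marginal_risk_b > 1)
    stopf("marginal_risk + marginal_risk_b must be <= 1")
  structure(list(variable_a = variable_a, level_a = level_a,
                 variable_b = variable_b, level_b = level_b,
                 joint_risk = joint_risk, marginal_risk = marginal_risk,
                 marginal_risk_b = marginal_risk_b),
            class = "pave_pattern")
}

#' Synthetic cohort specification
#'
#' Defaults describe a mortality-style desk-scale cohort: 100 cases with
#' 1:3 age/gender matched controls, a 48 h observation window behind a
#' 10 h hold-off, about 34 collections per patient inside the window,
#' and 30% missingness per (collection, variable) cell.
#'
#' @param variables Variable dictionary (default the eight vitals of
#'   [default_variable_dict()]).
#' @param n_cases Number of case patients.
#' @param control_ratio Matched controls per case.
#' @param observation_hours,holdoff_hours Window geometry (hours).
#' @param mean_collections Expected number of collections inside the
#'   observation window.
#' @param missing_rate Probability that a collection omits a variable:
#'   a scalar, or a named vector with one entry per variable.
#' @param base_sd_frac Within-normal baseline spread, as a fraction of
#'   the normal-range width.
#' @param noise_sd_frac Additional measurement noise, same units.
#' @param distractor_rate Expected number of mild label-independent
#'   out-of-range excursion collections per patient and variable.
#' @param mild_range,extreme_range Excursion depth as a fraction of the
#'   out-of-range side span: mild distractor excursions land in the
#'   inner part of the side, planted (signal) excursions in the outer
#'   part, with a gap between them so the side-median split is stable.
#' @param joint_collections_mean The number of collections carrying a
#'   planted excursion episode is `1 + Poisson(joint_collections_mean)`;
#'   the default gives sustained episodes of about 8 collections
#'   (roughly 11 h), the way genuine clinical deterioration persists
#'   across consecutive vital-sign checks.
#' @param signal_always_observed If `TRUE`, planted excursion cells
#'   bypass missingness; with the default sustained episodes this is
#'   unnecessary and missingness is applied uniformly (`FALSE`).
#' @param pair_gap_hours Minimum separation, in hours, between a mild
#'   distractor excursion of one pattern variable and any abnormal
#'   collection of its partner, so that no accidental pair
#'   co-occurrence arises outside planted joint episodes.
#' @param baseline_risk Probability that a control nevertheless carries
#'   the joint pattern (label noise; keeps the task imperfect).
#' @param patterns List of [planted_pattern()]s (may be empty).
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return A list of class `pave_synth_spec`.
#' @export
synthetic_spec <- function(variables = default_variable_dict(),
                           n_cases = 100L, control_ratio = 3L,
                           observation_hours = 48, holdoff_hours = 10,
                           mean_collections = 34, missing_rate = 0.3,
                           base_sd_frac = 0.125, noise_sd_frac = 0.05,
                           distractor_rate = 3.5,
                           mild_range = c(0.10, 0.45),
                           extreme_range = c(0.55, 0.95),
                           joint_collections_mean = 7,
                           pair_gap_hours = 1,
                           signal_always_observed = FALSE,
                           baseline_risk = 0.01,
                           patterns = list(planted_pattern()),
                           seed = 1L) {
  stopifnot(n_cases >= 1, control_ratio >= 1,
            all(missing_rate >= 0), all(missing_rate <= 1),
            baseline_risk >= 0, baseline_risk <= 1)
  if (length(missing_rate) > 1L &&
      !all(names(missing_rate) %in% names(variables)))
    stopf("per-variable missing_rate must be named by variable_id")
  for (pt in patterns) {
    stopifnot(inherits(pt, "pave_pattern"))
    if (!pt$variable_a %in% names(variables) ||
        !pt$variable_b %in% names(variables))
      stopf("pattern variables must be in the dictionary")
  }
  structure(list(variables = variables, n_cases = as.integer(n_cases),
                 control_ratio = as.integer(control_ratio),
                 observation_hours = observation_hours,
                 holdoff_hours = holdoff_hours,
                 mean_collections = mean_collections,
                 missing_rate = missing_rate,
                 base_sd_frac = base_sd_frac, noise_sd_frac = noise_sd_frac,
                 distractor_rate = distractor_rate,
                 mild_range = mild_range, extreme_range = extreme_range,
                 joint_collections_mean = joint_collections_mean,
                 pair_gap_hours = pair_gap_hours,
                 signal_always_observed = isTRUE(signal_always_observed),
                 baseline_risk = baseline_risk, patterns = patterns,
                 seed = as.integer(seed)),
            class = "pave_synth_spec")
}

level_side <- function(level) {
  if (level %in% c("high", "very_high")) "high"
  else if (level %in% c("low", "very_low")) "low"
  else stopf("a planted level must be out of range, got '%s'", level)
}

# excursion value on a side at depth u (fraction of the side span)
excursion_value <- function(spec_var, side, u) {
  if (side == "high") spec_var$normal_high + u * (spec_var$v_max - spec_var$normal_high)
  else spec_var$normal_low - u * (spec_var$normal_low - spec_var$v_min)
}

runif_range <- function(n, r) stats::runif(n, r[1L], r[2L])

#' Simulate one patient stream
#'
#' Draws demographics uniformly, collection times as exponential
#' inter-arrivals spanning the observation window plus the hold-off and
#' a 12 h lead-in (so that window extraction is exercised), baseline
#' values inside each variable's normal range, mild label-independent
#' distractor excursions for every variable, and the planted-pattern
#' machinery: with probability `joint_risk` (cases) or `baseline_risk`
#' (controls) the patient carries a sustained episode of co-occurring
#' extreme excursions of both pattern variables in shared in-window
#' collections; every other patient carries at most one lone extreme
#' episode of a single pattern variable, of the same length, at the
#' class-independent `marginal_risk` rate per variable; and mild
#' distractors of one pattern variable stay `pair_gap_hours` away from
#' the partner's abnormal collections. Missingness is applied last,
#' uniformly over cells (unless `signal_always_observed` forces planted
#' cells to be observed; sustained episodes survive missingness anyway).
#'
#' Uses the current RNG state; seed the generator (or call via
#' [simulate_cohort()]) for reproducibility.
#'
#' @param spec A [synthetic_spec()].
#' @param is_case Logical: simulate a case (label 1) or control.
#' @param patient_id Identifier for the patient.
#' @param demographics Optional list with `gender` and `age_group` to
#'   force a stratum (used when topping up matching pools).
#' @return A [new_patient()].
#' @export
simulate_patient <- function(spec, is_case, patient_id = "P1",
                             demographics = NULL) {
  vars <- spec$variables
  ids <- names(vars)
  if (is.null(demographics))
    demographics <- list(
      gender = sample(c("male", "female"), 1L),
      age_group = sample(PAVE_AGE_GROUPS[5:10], 1L))
  anchor <- 0
  win_start <- anchor - spec$holdoff_hours - spec$observation_hours
  t0 <- win_start - 12
  rate <- spec$mean_collections / spec$observation_hours
  gaps <- stats::rexp(ceiling((anchor - t0) * rate * 2 + 20), rate)
  times <- t0 + cumsum(gaps)
  times <- round(times[times < anchor], 3)
  nc <- length(times)
  if (!nc)
    return(new_patient(patient_id, demographics$gender,
                       demographics$age_group, label = as.integer(is_case),
                       anchor_time = anchor))
  in_window <- times >= win_start & times < anchor - spec$holdoff_hours

  nv <- length(ids)
  value <- matrix(NA_real_, nc, nv, dimnames = list(NULL, ids))
  forced <- matrix(FALSE, nc, nv, dimnames = list(NULL, ids))
  for (v in seq_len(nv)) {
    sv <- vars[[ids[v]]]
    if (sv$kind != "real") { value[, v] <- 1; next }
    has_nr <- !is.na(sv$normal_low)
    mid <- if (has_nr) (sv$normal_low + sv$normal_high) / 2
           else (sv$v_min + sv$v_max) / 2
    width <- if (has_nr) sv$normal_high - sv$normal_low
             else (sv$v_max - sv$v_min) / 4
    value[, v] <- mid + stats::rnorm(nc, 0, width * spec$base_sd_frac) +
      stats::rnorm(nc, 0, width * spec$noise_sd_frac)
  }

  pattern_vars <- unlist(lapply(spec$patterns,
                                function(p) c(p$variable_a, p$variable_b)))
  excursed <- matrix(FALSE, nc, nv, dimnames = list(NULL, ids))
  place_excursions <- function(var_id, side, n_exc, depth_range, force,
                               cand = !excursed[, var_id]) {
    ok <- which(cand & !excursed[, var_id])
    if (!length(ok) || n_exc < 1L) return(invisible(integer()))
    pick <- if (length(ok) == 1L) ok else sample(ok, min(n_exc, length(ok)))
    sv <- vars[[var_id]]
    value[pick, var_id] <<- excursion_value(sv, side,
                                            runif_range(length(pick), depth_range))
    excursed[pick, var_id] <<- TRUE
    if (force) forced[pick, var_id] <<- TRUE
    invisible(pick)
  }
  # Planted pattern machinery. Cases carry co-occurring (same
  # collection) extreme excursion episodes of both pattern variables
  # with probability joint_risk; controls with probability
  # baseline_risk. Every other patient, in either class, carries at
  # most ONE lone extreme episode (variable a or b, each with the
  # class-independent marginal rate), so a single variable at its
  # planted level is common in both classes and only the co-occurrence
  # of the pair is strongly label-informative. Mild distractor
  # excursions of a pattern variable are additionally kept
  # pair_gap_hours away from the partner's abnormal collections so no
  # accidental co-occurrence arises.
  for (pt in spec$patterns) {
    side_a <- level_side(pt$level_a); side_b <- level_side(pt$level_b)
    p_joint <- if (is_case) pt$joint_risk else spec$baseline_risk
    va <- pt$variable_a; vb <- pt$variable_b
    u <- stats::runif(1)
    config <- if (u < p_joint) "joint" else {
      u2 <- stats::runif(1)
      if (u2 < pt$marginal_risk) "a"
      else if (u2 < pt$marginal_risk + pt$marginal_risk_b) "b"
      else "none"
    }
    force_sig <- spec$signal_always_observed
    if (config == "joint") {
      n_sig <- 1L + stats::rpois(1L, spec$joint_collections_mean)
      cand <- which(in_window)
      pick <- if (length(cand) <= 1L) cand
              else sample(cand, min(n_sig, length(cand)))
      for (vs in list(list(va, side_a), list(vb, side_b))) {
        value[pick, vs[[1L]]] <-
          excursion_value(vars[[vs[[1L]]]], vs[[2L]],
                          runif_range(length(pick), spec$extreme_range))
        excursed[pick, vs[[1L]]] <- TRUE
        if (force_sig) forced[pick, vs[[1L]]] <- TRUE
      }
    } else if (config != "none") {
      lone <- if (config == "a") list(va, side_a) else list(vb, side_b)
      n_sig <- 1L + stats::rpois(1L, spec$joint_collections_mean)
      place_excursions(lone[[1L]], lone[[2L]], n_sig, spec$extreme_range,
                       force = force_sig, cand = in_window)
    }
    # mild distractors, kept clear of the partner's abnormal collections
    apart_from <- function(partner)
      in_window & !vapply(times, function(t)
        any(abs(t - times[excursed[, partner]]) < spec$pair_gap_hours), FALSE)
    for (vs in list(list(va, side_a, vb), list(vb, side_b, va))[sample.int(2L)]) {
      place_excursions(vs[[1L]], vs[[2L]],
                       stats::rpois(1L, spec$distractor_rate),
                       spec$mild_range, force = FALSE,
                       cand = apart_from(vs[[3L]]))
    }
  }
  for (v in setdiff(ids, pattern_vars)) {
    sv <- vars[[v]]
    if (sv$kind != "real" || is.na(sv$normal_low)) next
    sides <- c(if (sv$normal_high < sv$v_max) "high",
               if (sv$normal_low > sv$v_min) "low")
    if (!length(sides)) next
    n_exc <- stats::rpois(1L, spec$distractor_rate)
    if (n_exc)
      place_excursions(v, sample(sides, 1L), n_exc, spec$mild_range,
                       force = FALSE)
  }

  # clamp to physiologic range, then apply missingness to non-signal cells
  for (v in seq_len(nv)) {
    sv <- vars[[ids[v]]]
    if (sv$kind == "real")
      value[, v] <- round(clamp(value[, v], sv$v_min, sv$v_max), 2)
  }
  mr <- if (length(spec$missing_rate) > 1L) {
    m <- rep(0, nv); names(m) <- ids
    m[names(spec$missing_rate)] <- spec$missing_rate
    m
  } else rep(spec$missing_rate, nv)
  present <- matrix(stats::runif(nc * nv) >= rep(mr, each = nc), nc, nv) | forced

  idx <- which(present, arr.ind = TRUE)
  events <- data.frame(
    variable_id = ids[idx[, 2L]],
    value = value[idx],
    time = times[idx[, 1L]],
    collection_id = idx[, 1L],
    stringsAsFactors = FALSE)
  new_patient(patient_id, demographics$gender, demographics$age_group,
              events, label = as.integer(is_case), anchor_time = anchor)
}

#' Simulate a matched case-control cohort
#'
#' Simulates `n_cases` case streams and a control pool, then assembles
#' the cohort with [match_controls()] so each case gets
#' `control_ratio` age/gender-identical controls. The pool is topped up
#' per demographic stratum until every case can be matched, so the
#' result always contains exactly `n_cases * (1 + control_ratio)`
#' patients with label prevalence `1 / (1 + control_ratio)`. The whole
#' cohort is a deterministic function of the spec (including its
#' `seed`).
#'
#' @param spec A [synthetic_spec()].
#' @return A [new_cohort()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "pave_synth_spec"))
  with_seed(spec$seed, {
    cases <- lapply(seq_len(spec$n_cases), function(i)
      simulate_patient(spec, TRUE, sprintf("case_%04d", i)))
    pool <- lapply(seq_len(spec$n_cases * spec$control_ratio), function(i)
      simulate_patient(spec, FALSE, sprintf("ctrl_%04d", i)))
    stratum <- function(p) paste(p$demographics$age_group,
                                 p$demographics$gender, sep = "|")
    need <- table(vapply(cases, stratum, "")) * spec$control_ratio
    have <- table(factor(vapply(pool, stratum, ""), levels = names(need)))
    extra <- 0L
    for (s in names(need)) {
      deficit <- need[[s]] - have[[s]]
      if (deficit > 0) {
        parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
        for (j in seq_len(deficit)) {
          extra <- extra + 1L
          pool[[length(pool) + 1L]] <- simulate_patient(
            spec, FALSE, sprintf("ctrl_x%04d", extra),
            demographics = list(gender = parts[2L], age_group = parts[1L]))
        }
      }
    }
    match_controls(cases, pool, ratio = spec$control_ratio,
                   seed = spec$seed + 1L, variables = spec$variables,
                   observation_hours = spec$observation_hours,
                   holdoff_hours = spec$holdoff_hours)
  })
}

#' SIRS (sepsis-2) screening label
#'
#' Returns `TRUE` when at least two of the four SIRS criteria are met
#' anywhere in the patient's event stream:
#' temperature > 38.0 or < 35.0 degC; respiratory rate > 20/min or
#' PaCO2 < 32 mmHg; heart rate > 90/min; WBC > 12k or < 4k cells/uL or
#' band neutrophils > 10%. Missing variables count as criterion not
#' met.
#'
#' @param patient A [new_patient()].
#' @param variables Variable dictionary (used only to resolve ids; the
#'   thresholds are fixed clinical constants).
#' @return Logical.
#' @export
sirs_label <- function(patient, variables = sepsis_variable_dict()) {
  ev <- patient$events
  val <- function(id) ev$value[ev$variable_id == id]
  met <- c(
    any(val("temperature") > 38.0) || any(val("temperature") < 35.0),
    any(val("resp_rate") > 20) || any(val("paco2") < 32),
    any(val("heart_rate") > 90),
    any(val("wbc") > 12) || any(val("wbc") < 4) || any(val("band") > 10))
  sum(met) >= 2L
}

#' Planted-pattern indicator features of a cohort
#'
#' Diagnostic features certifying that a planted pattern is genuinely
#' interactive: for each patient, whether each pattern variable is ever
#' out of range on its planted side (`a_abnormal`, `b_abnormal`) and
#' whether both are out of range *in the same collection*
#' (`joint`). In a well-formed simulated cohort the single-variable
#' indicators are uninformative about the label while the joint
#' indicator is highly discriminative.
#'
#' @param cohort A [new_cohort()] (windowed internally).
#' @param pattern A [planted_pattern()].
#' @return Data frame with `patient_id`, `label`, `a_abnormal`,
#'   `b_abnormal`, `joint`.
#' @export
pattern_indicators <- function(cohort, pattern) {
  wc <- window_cohort(cohort, quiet = TRUE)
  va <- wc$variables[[pattern$variable_a]]
  vb <- wc$variables[[pattern$variable_b]]
  side_a <- level_side(pattern$level_a); side_b <- level_side(pattern$level_b)
  out_of <- function(values, sv, side) {
    if (side == "high") values > sv$normal_high else values < sv$normal_low
  }
  rows <- lapply(wc$patients, function(p) {
    ev <- p$events
    ia <- ev$variable_id == pattern$variable_a & out_of(ev$value, va, side_a)
    ib <- ev$variable_id == pattern$variable_b & out_of(ev$value, vb, side_b)
    joint <- length(intersect(ev$collection_id[ia], ev$collection_id[ib])) > 0L
    data.frame(patient_id = p$patient_id, label = p$label,
               a_abnormal = any(ia), b_abnormal = any(ib), joint = joint,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
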