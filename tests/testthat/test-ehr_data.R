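test_that("cohort files round-trip field for field", {
  coh <- small_sim_cohort()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(coh, f)
  coh2 <- read_cohort(f, variables = coh$variables,
                      observation_hours = coh$observation_hours,
                      holdoff_hours = coh$holdoff_hours)
  expect_equal(length(coh2$patients), length(coh$patients))
  for (i in seq_along(coh$patients))
    expect_equal(coh2$patients[[i]], coh$patients[[i]], tolerance = 0)

  # boolean event values and empty cohorts survive too
  p <- tiny_patient(events = tiny_events(c("antibiotic", "heart_rate"),
                                         c(1.0, 72.5), c(-20, -20), c(1L, 1L)))
  for (patients in list(list(p), list())) {
    c1 <- tiny_cohort(patients)
    write_cohort(c1, f)
    c2 <- read_cohort(f, variables = tiny_vars(), holdoff_hours = 10)
    expect_equal(c2$patients, c1$patients, tolerance = 0)
  }
})

test_that("malformed or invalid stream files are rejected with context", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"patient_id": "p1", not json', f)
  expect_error(read_cohort(f, variables = tiny_vars()), "line 1")

  writeLines(paste0('{"patient_id":"p1","label":0,"anchor_time":0,',
                    '"demographics":{"gender":"male","age_group":"60-69"},',
                    '"events":[["heart_rate",80,"NaN",1]]}'), f)
  expect_error(read_cohort(f, variables = tiny_vars()), "non-finite")

  writeLines(paste0('{"patient_id":"p1","label":0,"anchor_time":0,',
                    '"demographics":{"gender":"male","age_group":"60-69"},',
                    '"events":[["mystery_lab",1,0,1]]}'), f)
  expect_error(read_cohort(f, variables = tiny_vars()), "mystery_lab")
})

test_that("patients validate demographics, labels and event ordering", {
  expect_error(new_patient("p", "male", "60ish"), "age_group")
  expect_error(new_patient("p", "robot", "60-69"), "gender")
  expect_error(new_patient("p", "male", "60-69", label = 2), "label")
  # unsorted input events come back sorted by time then (collection, variable)
  ev <- tiny_events(c("temperature", "heart_rate", "heart_rate"),
                    c(37, 80, 90), c(-10, -30, -10), c(2L, 1L, 2L))
  p <- new_patient("p", "male", "60-69", ev)
  expect_equal(p$events$time, c(-30, -10, -10))
  expect_equal(p$events$variable_id[2:3], c("heart_rate", "temperature"))
})

test_that("age groups are decade bins with an open top bin", {
  expect_equal(age_group_of(c(0, 9, 10, 67, 89, 90, 104)),
               c("0-9", "0-9", "10-19", "60-69", "80-89", "90+", "90+"))
  expect_error(age_group_of(-1), "non-negative")
})

test_that("observation-window extraction keeps [anchor-holdoff-obs, anchor-holdoff)", {
  p <- tiny_patient(events = tiny_events("heart_rate", 80,
                                         c(-60, -40, -5, -2)), anchor = 0)
  w <- extract_observation_window(p, 48, 10)
  expect_equal(w$events$time, -40)
  expect_equal(w$label, p$label)
  expect_equal(w$demographics, p$demographics)

  # closed at the older edge, open at the newer edge
  p2 <- tiny_patient(events = tiny_events("heart_rate", 80, c(-48, 0)))
  expect_equal(extract_observation_window(p2, 48, 0)$events$time, -48)

  # everything inside the hold-off window is dropped
  p3 <- tiny_patient(events = tiny_events("heart_rate", 80, c(-5, -2)))
  expect_equal(nrow(extract_observation_window(p3, 48, 10)$events), 0L)

  # idempotence
  w2 <- extract_observation_window(w, 48, 10)
  expect_identical(w2$events, w$events)
})

test_that("window_cohort drops and reports empty windows", {
  late <- tiny_patient("late", events = tiny_events("heart_rate", 80, -3))
  ok <- tiny_patient("ok", events = tiny_events("heart_rate", 80, -30))
  coh <- tiny_cohort(list(late, ok))
  expect_message(wc <- window_cohort(coh), "excluded 1")
  expect_equal(vapply(wc$patients, `[[`, "", "patient_id"), "ok")
})

test_that("time deltas are recency lags behind the latest event", {
  p <- tiny_patient(events = tiny_events("heart_rate", 80, c(0, 2, 5)))
  expect_equal(compute_time_deltas(p), c(5, 3, 0))
  expect_equal(compute_time_deltas(
    tiny_patient(events = tiny_events("heart_rate", 80, -7))), 0)
  expect_equal(compute_time_deltas(
    tiny_patient(events = tiny_events(c("heart_rate", "temperature"),
                                      c(80, 37), c(-7, -7), c(1L, 1L)))),
    c(0, 0))
  expect_error(compute_time_deltas(tiny_patient(events = empty_events_df())),
               "no events")
})

test_that("time deltas are non-negative and anti-monotone in event time", {
  coh <- window_cohort(small_sim_cohort(), quiet = TRUE)
  for (p in coh$patients[1:5]) {
    d <- compute_time_deltas(p)
    expect_true(all(d >= 0))
    expect_equal(d[which.max(p$events$time)], 0)
    expect_true(all(diff(d[order(p$events$time)]) <= 0))
  }
})

test_that("match_controls samples demographically identical controls", {
  mk <- function(id, gender = "male", age = "60-69", label = 0L)
    new_patient(id, gender, age,
                tiny_events("heart_rate", 80, -20), label, anchor_time = -100)
  case <- mk("case", label = 1L)
  case$anchor_time <- -5
  pool <- c(lapply(paste0("m", 1:5), mk),
            list(mk("f1", gender = "female"), mk("old", age = "80-89")))
  coh <- match_controls(list(case), pool, ratio = 3, seed = 7,
                        variables = tiny_vars())
  expect_length(coh$patients, 4L)
  ctrls <- coh$patients[-1]
  for (ct in ctrls) {
    expect_equal(ct$demographics, case$demographics)
    expect_equal(ct$anchor_time, case$anchor_time)  # case-anchored indexing
    expect_equal(ct$label, 0L)
  }
  # determinism under the seed
  coh2 <- match_controls(list(case), pool, ratio = 3, seed = 7,
                         variables = tiny_vars())
  expect_identical(vapply(coh2$patients, `[[`, "", "patient_id"),
                   vapply(coh$patients, `[[`, "", "patient_id"))

  # insufficient matches: the case is dropped with a warning
  expect_warning(
    short <- match_controls(list(case), pool[1:2], ratio = 3, seed = 7,
                            variables = tiny_vars()),
    "insufficient")
  expect_length(short$patients, 0L)
  expect_error(match_controls(list(case), pool, ratio = 0, seed = 1,
                              variables = tiny_vars()), "ratio")
})
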