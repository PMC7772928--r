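test_that("time embedding matches its closed form at anchor points", {
  cfg <- embedding_config(k = 4L, t_m = 48)
  # zero interval: sin dims are 0, cos dims are 1
  expect_equal(time_embed(0, cfg), c(0, 1, 0, 1))
  # t = t_m, k = 2: dimension 1 is cos(t_m * 1 / (t_m * 2)) = cos(0.5)
  expect_equal(time_embed(48, embedding_config(k = 2L, t_m = 48)),
               c(0, cos(0.5)), tolerance = 1e-12)
  expect_equal(time_embed(48, embedding_config(k = 2L, t_m = 48))[2],
               0.87758, tolerance = 1e-5)
  # t = t_m/2, k = 4: dimension with j = 2 is sin(0.5 * 2 / 4) = sin(0.25)
  expect_equal(time_embed(24, cfg)[3], sin(0.25), tolerance = 1e-12)
  expect_equal(time_embed(24, cfg)[3], 0.24740, tolerance = 1e-4)
})

test_that("time embedding validates and clamps its domain", {
  cfg <- embedding_config(k = 4L, t_m = 10)
  expect_error(time_embed(-1, cfg), ">= 0")
  expect_warning(v <- time_embed(25, cfg), "clamped")
  expect_equal(v, time_embed(10, cfg))
  expect_error(embedding_config(k = 3L), "even")
  expect_error(embedding_config(t_m = 0), "t_m")
})

test_that("value embedding depends only on the normalised value", {
  cfg <- embedding_config(k = 2L, t_m = 48)
  hr <- tiny_vars()$heart_rate
  temp <- tiny_vars()$temperature
  expect_equal(value_embed(hr$v_min, hr, cfg), c(0, 1))
  expect_equal(value_embed(hr$v_max, hr, cfg), c(0, cos(0.5)), tolerance = 1e-12)
  # same relative position of different ranges: identical embedding
  pos <- 0.37
  v1 <- value_embed(hr$v_min + pos * (hr$v_max - hr$v_min), hr, cfg)
  v2 <- value_embed(temp$v_min + pos * (temp$v_max - temp$v_min), temp, cfg)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_error(value_embed(1, list(v_min = 5, v_max = 5), cfg), "v_min < v_max")
  expect_error(value_embed(1, tiny_vars()$antibiotic, cfg), "real")
})

test_that("sinusoidal embeddings agree with the scalar-loop oracle and stay bounded", {
  set.seed(11)
  for (rep in 1:200) {
    k <- 2L * sample(1:8, 1)
    j_base <- sample(0:1, 1)
    t_m <- runif(1, 1, 100)
    t <- runif(1, 0, t_m)
    cfg <- embedding_config(k = k, t_m = t_m, j_base = j_base)
    got <- time_embed(t, cfg)
    expect_equal(got, oracle_sinusoid(t, t_m, k, j_base), tolerance = 1e-12)
    expect_true(all(abs(got) <= 1))
    vmin <- runif(1, -50, 50); vmax <- vmin + runif(1, 0.1, 300)
    val <- runif(1, vmin, vmax)
    expect_equal(value_embed(val, list(v_min = vmin, v_max = vmax), cfg),
                 oracle_sinusoid(val - vmin, vmax - vmin, k, j_base),
                 tolerance = 1e-12)
  }
})

test_that("value/event combination is linear for real and a bypass for boolean", {
  k <- 8L
  cfg <- embedding_config(k = k, t_m = 48)
  params <- init_pave_params(names(tiny_vars()), k, seed = 2)
  ev_real <- list(variable_id = "heart_rate", value = 120)
  ev_bool <- list(variable_id = "antibiotic", value = 1)

  p1 <- params
  p1$W_v <- matrix(0, k, k); p1$W_e <- diag(k); p1$b_e <- numeric(k)
  expect_equal(combine_event_value(ev_real, tiny_vars()$heart_rate, p1, cfg),
               unname(params$event_table["heart_rate", ]))

  # boolean events ignore the combination layer entirely
  p2 <- params
  p2$W_v <- matrix(rnorm(k * k), k, k)
  expect_equal(combine_event_value(ev_bool, tiny_vars()$antibiotic, p2, cfg),
               params$event_table["antibiotic", ])

  p3 <- params
  p3$event_table[] <- 0; p3$W_v[] <- 0; p3$W_e[] <- 0; p3$b_e[] <- 0
  expect_equal(combine_event_value(ev_real, tiny_vars()$heart_rate, p3, cfg),
               numeric(k))
  expect_error(combine_event_value(list(variable_id = "nope", value = 1),
                                   tiny_vars()$heart_rate, params, cfg),
               "not in")
})

test_that("demographic attention softmaxes attribute scores", {
  k <- 6L
  params <- init_pave_params("heart_rate", k, seed = 3)
  demo <- list(gender = "female", age_group = "70-79")
  # equal scores: weights 0.5/0.5 and output the mean of the two rows
  p1 <- params; p1$W_vd[] <- 0
  res <- demographic_attend(demo, numeric(k), p1)
  expect_equal(unname(res$weights), c(0.5, 0.5))
  rows <- params$demo_table[c("gender:female", "age:70-79"), ]
  expect_equal(res$v_da, unname(colMeans(rows)))
  # scores (ln 3, 0): weights (0.75, 0.25)
  p2 <- params
  p2$W_vd <- c(1, rep(0, k - 1)); p2$W_ve[] <- 0
  p2$demo_table["gender:female", ] <- c(log(3), rep(0, k - 1))
  p2$demo_table["age:70-79", ] <- 0
  expect_equal(unname(demographic_attend(demo, numeric(k), p2)$weights),
               c(0.75, 0.25), tolerance = 1e-12)
})

test_that("demographic weights are a probability vector for random inputs", {
  set.seed(21)
  params <- init_pave_params("heart_rate", 8L, seed = 9)
  for (i in 1:25) {
    demo <- list(gender = sample(c("male", "female", "other"), 1),
                 age_group = sample(age_group_of(runif(1, 0, 99)), 1))
    w <- demographic_attend(demo, rnorm(8), params)$weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-5)
  }
})

test_that("event fusion combines the three branches linearly", {
  k <- 8L
  cfg <- embedding_config(k = k, t_m = 48)
  params <- init_pave_params(names(tiny_vars()), k, seed = 4)
  ev <- list(variable_id = "temperature", value = 39.5)
  demo <- list(gender = "male", age_group = "60-69")
  spec <- tiny_vars()$temperature

  p1 <- params
  p1$W_qe <- diag(k); p1$W_qt[] <- 0; p1$W_qd[] <- 0; p1$b_q[] <- 0
  e1 <- embed_event(ev, 5, demo, spec, p1, cfg)
  expect_equal(e1$q, e1$v_e)
  expect_equal(e1$v_t, time_embed(5, cfg))
  expect_equal(e1$v_ev, value_embed(39.5, spec, cfg))

  p2 <- params
  p2$W_qe[] <- 0; p2$W_qt[] <- 0; p2$W_qd[] <- 0; p2$b_q <- rep(2.5, k)
  expect_equal(embed_event(ev, 5, demo, spec, p2, cfg)$q, rep(2.5, k))

  # determinism
  expect_identical(embed_event(ev, 5, demo, spec, params, cfg),
                   embed_event(ev, 5, demo, spec, params, cfg))
})
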