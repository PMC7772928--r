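k_test <- 8L

rand_params <- function(seed, k = k_test)
  init_pave_params(names(tiny_vars()), k, seed = seed)

test_that("self-attention handles singleton and symmetric cases exactly", {
  params <- rand_params(31)
  q1 <- matrix(rnorm(k_test), 1, k_test)
  r1 <- self_attend(q1, params)
  expect_equal(r1$alpha, matrix(1, 1, 1))
  V1 <- drop(q1 %*% params$W_V) + params$b_V
  expect_equal(drop(r1$P), 2 * V1)

  # all scores equal (zero queries): uniform attention
  p0 <- params; p0$W_Q[] <- 0; p0$b_Q[] <- 0
  q2 <- matrix(rnorm(2 * k_test), 2, k_test)
  r2 <- self_attend(q2, p0)
  expect_equal(r2$alpha, matrix(0.5, 2, 2))
  V <- sweep(q2 %*% params$W_V, 2, params$b_V, `+`)
  expect_equal(r2$P, V + matrix(colMeans(V), 2, k_test, byrow = TRUE))

  expect_error(self_attend(matrix(numeric(), 0, k_test), params), "one event")
})

test_that("self-attention matches the brute-force double-loop oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(1:5, 1)
    params <- rand_params(rep)
    q <- matrix(rnorm(n * k_test), n, k_test)
    got <- self_attend(q, params)
    want <- oracle_self_attend(q, params)
    expect_equal(got$P, want$P, tolerance = 1e-10)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-10)
  }
})

test_that("excluding the self pair empties the attention diagonal", {
  params <- rand_params(5)
  q <- matrix(rnorm(3 * k_test), 3, k_test)
  r <- self_attend(q, params, include_self = FALSE)
  expect_equal(diag(r$alpha), rep(0, 3))
  expect_equal(rowSums(r$alpha), rep(1, 3))
  expect_error(self_attend(q[1, , drop = FALSE], params, include_self = FALSE),
               "single event")
})

test_that("pattern attention pools with softmax weights", {
  params <- rand_params(41)
  P <- matrix(rnorm(3 * k_test), 3, k_test)
  p0 <- params; p0$W_p[] <- 0
  r <- pattern_attend(P, p0)
  expect_equal(r$gamma, rep(1 / 3, 3))
  expect_equal(r$h, colMeans(P))

  r1 <- pattern_attend(P[1, , drop = FALSE], params)
  expect_equal(r1$gamma, 1)
  expect_equal(r1$h, P[1, ])

  # scores (ln 3, 0) give weights (0.75, 0.25)
  p2 <- params
  p2$W_p <- c(1, rep(0, k_test - 1)); p2$b_p <- 0
  P2 <- rbind(c(log(3), rep(0, k_test - 1)), rep(0, k_test))
  expect_equal(pattern_attend(P2, p2)$gamma, c(0.75, 0.25), tolerance = 1e-12)
})

test_that("risk head and loss follow their closed forms", {
  params <- rand_params(51)
  p <- params; p$W_h[] <- 0; p$b_h <- 0
  expect_equal(predict_risk(rnorm(k_test), p), 0.5)
  p$b_h <- log(3)
  expect_equal(predict_risk(rnorm(k_test), p), 0.75, tolerance = 1e-12)
  p$b_h <- 30
  expect_gt(predict_risk(rnorm(k_test), p), 1 - 1e-12)

  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 0), 2.3026, tolerance = 1e-4)
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)
  expect_error(bce_loss(0.5, 0.3), "0 or 1")
})

test_that("forward traces conserve attention mass and respect permutations", {
  coh <- small_sim_cohort()
  model <- pave_model(coh, k = 16, seed = 2)
  wc <- window_cohort(coh, quiet = TRUE)
  p <- wc$patients[[1]]
  tr <- pave_forward(p, model)
  expect_true(all(abs(rowSums(tr$alpha) - 1) < 1e-5))
  expect_lt(abs(sum(tr$gamma) - 1), 1e-5)
  expect_true(tr$y > 0 && tr$y < 1)

  # permuting stored event order leaves the output unchanged
  perm <- p
  ord <- sample(nrow(p$events))
  perm$events <- p$events[ord, ]
  expect_equal(pave_forward(perm, model)$y, tr$y, tolerance = 1e-10)

  # duplicated patient: identical trace
  expect_identical(pave_forward(p, model)$y, tr$y)

  empty <- p; empty$events <- empty$events[0, ]
  expect_error(pave_forward(empty, model), "no events")
})

test_that("hand-written gradients agree with finite differences", {
  # boolean events included so the bypass path is exercised
  ev <- tiny_events(c("heart_rate", "temperature", "antibiotic"),
                    c(120, 39.5, 1), c(-30, -20, -12))
  p <- tiny_patient(events = ev)
  coh <- tiny_cohort(list(p), holdoff = 0)
  for (variant in list(model_variant(), model_variant(FALSE, TRUE),
                       model_variant(TRUE, FALSE))) {
    model <- pave_model(coh, k = 6, seed = 13, variant = variant)
    prep <- pave:::prepare_patient(p, model$variables, model$norm,
                                   model$embed_config, variant)
    params <- model$params
    fwd <- pave:::pave_fwd(prep, params, variant, want_cache = TRUE)
    gr <- pave:::pave_bwd(fwd, params, variant, pave:::zero_grads(params))
    loss_at <- function(pp)
      bce_loss(pave:::pave_fwd(prep, pp, variant)$y, prep$label)
    eps <- 1e-6
    set.seed(99)
    for (nm in names(params)) {
      idx <- seq_along(params[[nm]])
      if (length(idx) > 10) idx <- sample(idx, 10)
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                     label = sprintf("d/d%s[%d] (%s)", nm, i,
                                     pave:::variant_name(variant)))
      }
    }
  }
})

test_that("the no-time variant ignores event times entirely", {
  coh <- small_sim_cohort()
  wc <- window_cohort(coh, quiet = TRUE)
  p <- wc$patients[[1]]
  m_not <- pave_model(coh, k = 16, seed = 6, variant = model_variant(FALSE, TRUE))
  m_full <- pave_model(coh, k = 16, seed = 6)

  shifted <- p
  shifted$events$time <- p$events$time + 5
  shifted$anchor_time <- p$anchor_time + 5
  # uniform translation: bit-stable for the no-time variant
  expect_identical(pave_forward(shifted, m_not)$y, pave_forward(p, m_not)$y)

  # redraw times inside the window so the event set is unchanged but
  # every interval differs
  jit <- p
  set.seed(8)
  jit$events$time <- sort(runif(nrow(p$events), -57, -11))
  y_not <- pave_forward(jit, m_not)$y
  expect_identical(y_not, pave_forward(p, m_not)$y)
  # ... while the full model reacts to changed intervals
  expect_gt(abs(pave_forward(jit, m_full)$y - pave_forward(p, m_full)$y), 1e-8)
})

test_that("model checkpoints survive a save/load round trip", {
  coh <- small_sim_cohort()
  model <- pave_model(coh, k = 8, seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$params, model$params)
  wc <- window_cohort(coh, quiet = TRUE)
  expect_identical(pave_forward(wc$patients[[1]], m2)$y,
                   pave_forward(wc$patients[[1]], model)$y)
})
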