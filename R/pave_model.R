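# The pattern-attention network proper: a single self-attention layer
# over the per-event embeddings, a pattern-attention pooling layer, and
# a sigmoid risk head, together with the analytic backward pass used by
# the trainer (gradients are derived by hand; a finite-difference check
# lives in the test suite).

#' Model variant flags
#'
#' The full model uses both the sinusoidal time embedding and the
#' sinusoidal value embedding. Setting `use_time_embedding = FALSE`
#' zeroes the time branch (the no-time ablation); setting
#' `use_value_embedding = FALSE` replaces the sinusoidal value embedding
#' by a learned linear map of the min-max normalised scalar value (the
#' no-value-embedding ablation, the stream analogue of feeding
#' mean-imputed raw values through a linear layer).
#'
#' @param use_time_embedding,use_value_embedding Logical flags.
#' @return A list of class `pave_variant`.
#' @export
model_variant <- function(use_time_embedding = TRUE,
                          use_value_embedding = TRUE) {
  structure(list(use_time_embedding = isTRUE(use_time_embedding),
                 use_value_embedding = isTRUE(use_value_embedding)),
            class = "pave_variant")
}

variant_name <- function(v) {
  if (v$use_time_embedding && v$use_value_embedding) "PAVE"
  else if (!v$use_time_embedding && v$use_value_embedding) "PAVE-T"
  else if (v$use_time_embedding && !v$use_value_embedding) "PAVE-V"
  else "PAVE-TV"
}

#' Self-attention over event embeddings
#'
#' Projects the `n x k` event embedding matrix `q` to queries, keys and
#' values (`Q = q W_Q + b_Q`, etc.), scores every ordered pair with the
#' dot product `beta_ij = Q_i . K_j`, normalises each row with a softmax
#' (the diagonal `j = i` is included by default; `include_self = FALSE`
#' excludes it for sensitivity analyses), and returns the residual
#' pattern vectors `P_i = V_i + sum_j alpha_ij V_j`. No `1/sqrt(k)`
#' scaling is applied to the scores unless `scaled = TRUE`.
#'
#' @param q `n x k` matrix of event embeddings, `n >= 1`.
#' @param params Parameters from [init_pave_params()].
#' @param include_self Include the self pair in each softmax (default).
#' @param scaled Divide scores by `sqrt(k)` (off by default).
#' @return List with `P` (`n x k`) and `alpha` (`n x n`, row-stochastic).
#' @export
self_attend <- function(q, params, include_self = TRUE, scaled = FALSE) {
  q <- rbind(q)
  n <- nrow(q)
  if (n < 1L) stopf("self_attend: need at least one event")
  Q <- q %*% params$W_Q
  Q <- sweep(Q, 2L, params$b_Q, `+`)
  K <- sweep(q %*% params$W_K, 2L, params$b_K, `+`)
  V <- sweep(q %*% params$W_V, 2L, params$b_V, `+`)
  B <- tcrossprod(Q, K)
  if (scaled) B <- B / sqrt(ncol(q))
  if (!include_self) {
    if (n == 1L) stopf("self_attend: cannot exclude self with a single event")
    diag(B) <- -Inf
  }
  alpha <- softmax_rows(B)
  list(P = V + alpha %*% V, alpha = alpha)
}

#' Pattern attention pooling
#'
#' Scores each pattern vector with `theta_i = P_i . W_p + b_p`,
#' softmaxes the scores into pattern weights `gamma`, and pools
#' `h = sum_i gamma_i P_i` into a single patient representation.
#'
#' @param P `n x k` matrix of pattern vectors.
#' @param params Parameters from [init_pave_params()].
#' @return List with `h` (`k`-vector) and `gamma` (`n`-vector summing
#'   to 1).
#' @export
pattern_attend <- function(P, params) {
  P <- rbind(P)
  theta <- drop(P %*% params$W_p) + params$b_p
  gamma <- softmax_vec(theta)
  list(h = drop(crossprod(P, gamma)), gamma = gamma)
}

#' Risk head
#'
#' `y = sigmoid(h . W_h + b_h)`, a probability in (0, 1).
#'
#' @param h Patient representation (`k`-vector).
#' @param params Parameters from [init_pave_params()].
#' @return Scalar risk probability.
#' @export
predict_risk <- function(h, params) {
  stats::plogis(sum(h * params$W_h) + params$b_h)
}

#' Binary cross-entropy loss
#'
#' `L = -(y_true log y + (1 - y_true) log(1 - y))`, with the prediction
#' clamped to `[1e-7, 1 - 1e-7]` to keep the logs finite.
#'
#' @param y Predicted probability.
#' @param y_true Ground-truth label, 0 or 1.
#' @return Non-negative loss.
#' @export
bce_loss <- function(y, y_true) {
  if (!all(y_true %in% c(0, 1))) stopf("y_true must be 0 or 1")
  y <- clamp(y, 1e-7, 1 - 1e-7)
  -(y_true * log(y) + (1 - y_true) * log(1 - y))
}

# ---- patient preparation -----------------------------------------------
# Everything about a windowed patient that does not depend on learnable
# parameters is computed once: sinusoidal time/value embeddings, event
# table row indices, demographic row indices, normalised scalar values.

prepare_patient <- function(patient, variables, norm, config, variant) {
  ev <- patient$events
  n <- nrow(ev)
  if (!n) stopf("patient '%s': no events in window", patient$patient_id)
  deltas <- compute_time_deltas(patient)
  deltas <- pmin(deltas, config$t_m)
  var_idx <- match(ev$variable_id, rownames(norm$stats))
  if (anyNA(var_idx))
    stopf("patient '%s': variable(s) outside the model vocabulary",
          patient$patient_id)
  st <- norm$stats
  vmin <- st$v_min[var_idx]; vrange <- st$v_range[var_idx]
  is_real <- st$is_real[var_idx]
  s <- clamp((ev$value - vmin) / vrange, 0, 1)
  s[!is_real] <- 0
  k <- config$k
  Tsin <- if (variant$use_time_embedding)
    sinusoid_embed(deltas, config$t_m, k, config$j_base)
  else matrix(0, n, k)
  Vsin <- if (variant$use_value_embedding) {
    # sinusoid of the normalised value: reuse the shared map with range 1
    m <- sinusoid_embed(s, 1, k, config$j_base)
    m[!is_real, ] <- 0
    m
  } else NULL
  d_idx <- match(c(paste0("gender:", patient$demographics$gender),
                   paste0("age:", patient$demographics$age_group)),
                 demo_rows())
  list(n = n, var_idx = var_idx, is_real = is_real, s = s,
       Tsin = Tsin, Vsin = Vsin, d_idx = d_idx,
       label = patient$label, patient_id = patient$patient_id,
       events = ev, deltas = deltas)
}

# normalisation statistics fitted on a training split: per-variable
# observed min/max (for value normalisation), mean (for the
# no-value-embedding ablation), and the maximum time delta t_m.
fit_normalization <- function(patients, variables) {
  ids <- names(variables)
  st <- data.frame(row.names = ids,
                   v_min = NA_real_, v_max = NA_real_, mean = NA_real_,
                   is_real = vapply(variables, function(v) v$kind == "real", FALSE))
  vals <- list()
  t_max <- 0
  for (p in patients) {
    if (nrow(p$events)) t_max <- max(t_max, max(compute_time_deltas(p)))
    sp <- split(p$events$value, p$events$variable_id)
    for (id in names(sp)) vals[[id]] <- c(vals[[id]], sp[[id]])
  }
  for (id in ids) {
    v <- variables[[id]]
    if (v$kind != "real") next
    x <- vals[[id]]
    if (is.null(x)) {
      st[id, "v_min"] <- v$v_min; st[id, "v_max"] <- v$v_max
      st[id, "mean"] <- (v$v_min + v$v_max) / 2
    } else {
      x <- clamp(x, v$v_min, v$v_max)
      st[id, "v_min"] <- min(x); st[id, "v_max"] <- max(x)
      st[id, "mean"] <- mean(x)
      if (st[id, "v_min"] == st[id, "v_max"]) {
        st[id, "v_min"] <- v$v_min; st[id, "v_max"] <- v$v_max
      }
    }
  }
  st$v_range <- st$v_max - st$v_min
  st$v_range[!st$is_real] <- 1
  list(stats = st, t_m = if (t_max > 0) t_max else 48)
}

#' Fit normalisation statistics on a training split
#'
#' Computes, from the training patients only, the per-variable observed
#' minimum/maximum (clamped to the dictionary's physiologic range) used
#' to normalise values before embedding, the per-variable mean used by
#' the no-value-embedding ablation, and the maximum observed time delta
#' `t_m`. Keeping these statistics train-split-only prevents test-set
#' leakage; degenerate splits (a constant or unobserved variable) fall
#' back to the dictionary range.
#'
#' @param cohort A windowed [new_cohort()] (training split).
#' @return List with `stats` (data frame keyed by variable) and `t_m`.
#' @export
fit_cohort_normalization <- function(cohort) {
  stopifnot(inherits(cohort, "pave_cohort"))
  fit_normalization(cohort$patients, cohort$variables)
}

# ---- fast forward / backward -------------------------------------------

# forward pass over a prepared patient. Returns the risk and, when
# want_cache, every intermediate needed for the backward pass.
pave_fwd <- function(prep, params, variant, want_cache = FALSE) {
  n <- prep$n
  E <- params$event_table[prep$var_idx, , drop = FALSE]
  Vev <- if (variant$use_value_embedding) prep$Vsin
         else outer(prep$s, params$w_val) +
              matrix(params$b_val, n, length(params$b_val), byrow = TRUE)
  Ve <- Vev %*% params$W_v + E %*% params$W_e
  Ve <- sweep(Ve, 2L, params$b_e, `+`)
  if (any(!prep$is_real)) Ve[!prep$is_real, ] <- E[!prep$is_real, , drop = FALSE]
  D2 <- params$demo_table[prep$d_idx, , drop = FALSE]
  beta_d <- matrix(drop(D2 %*% params$W_vd), n, 2L, byrow = TRUE) +
    drop(Ve %*% params$W_ve)
  Ad <- softmax_rows(beta_d)
  Vda <- Ad %*% D2
  Qm <- Ve %*% params$W_qe + prep$Tsin %*% params$W_qt + Vda %*% params$W_qd
  Qm <- sweep(Qm, 2L, params$b_q, `+`)
  Qa <- sweep(Qm %*% params$W_Q, 2L, params$b_Q, `+`)
  Ka <- sweep(Qm %*% params$W_K, 2L, params$b_K, `+`)
  Va <- sweep(Qm %*% params$W_V, 2L, params$b_V, `+`)
  B <- tcrossprod(Qa, Ka)
  A <- softmax_rows(B)
  P <- Va + A %*% Va
  theta <- drop(P %*% params$W_p) + params$b_p
  g <- softmax_vec(theta)
  h <- drop(crossprod(P, g))
  logit <- sum(h * params$W_h) + params$b_h
  y <- stats::plogis(logit)
  out <- list(y = y, alpha = A, gamma = g, P = P, h = h, logit = logit)
  if (want_cache)
    out$cache <- list(E = E, Vev = Vev, Ve = Ve, D2 = D2, Ad = Ad, Vda = Vda,
                      Qm = Qm, Qa = Qa, Ka = Ka, Va = Va, A = A, P = P,
                      g = g, h = h, prep = prep)
  out
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# accumulate into `gr` the gradient of (scale * BCE(y, label)) for one
# prepared patient; returns the updated gradient list.
pave_bwd <- function(fwd, params, variant, gr, scale = 1) {
  cc <- fwd$cache
  prep <- cc$prep
  n <- prep$n
  dlogit <- scale * (fwd$y - prep$label)

  gr$W_h <- gr$W_h + dlogit * cc$h
  gr$b_h <- gr$b_h + dlogit
  dh <- dlogit * params$W_h

  dg <- drop(cc$P %*% dh)
  dP <- tcrossprod(cc$g, dh)
  dtheta <- cc$g * (dg - sum(cc$g * dg))
  gr$W_p <- gr$W_p + drop(crossprod(cc$P, dtheta))
  gr$b_p <- gr$b_p + sum(dtheta)
  dP <- dP + tcrossprod(dtheta, params$W_p)

  dVa <- dP + crossprod(cc$A, dP)
  dA <- tcrossprod(dP, cc$Va)
  dB <- cc$A * (dA - rowSums(cc$A * dA))
  dQa <- dB %*% cc$Ka
  dKa <- crossprod(dB, cc$Qa)

  gr$W_Q <- gr$W_Q + crossprod(cc$Qm, dQa)
  gr$b_Q <- gr$b_Q + colSums(dQa)
  gr$W_K <- gr$W_K + crossprod(cc$Qm, dKa)
  gr$b_K <- gr$b_K + colSums(dKa)
  gr$W_V <- gr$W_V + crossprod(cc$Qm, dVa)
  gr$b_V <- gr$b_V + colSums(dVa)
  dQm <- tcrossprod(dQa, params$W_Q) + tcrossprod(dKa, params$W_K) +
    tcrossprod(dVa, params$W_V)

  gr$W_qe <- gr$W_qe + crossprod(cc$Ve, dQm)
  if (variant$use_time_embedding)
    gr$W_qt <- gr$W_qt + crossprod(prep$Tsin, dQm)
  gr$W_qd <- gr$W_qd + crossprod(cc$Vda, dQm)
  gr$b_q <- gr$b_q + colSums(dQm)
  dVe <- tcrossprod(dQm, params$W_qe)
  dVda <- tcrossprod(dQm, params$W_qd)

  # demographic attention
  dAd <- tcrossprod(dVda, cc$D2)
  dD2 <- crossprod(cc$Ad, dVda)
  dbeta <- cc$Ad * (dAd - rowSums(cc$Ad * dAd))
  csb <- colSums(dbeta)
  dD2 <- dD2 + tcrossprod(csb, params$W_vd)
  gr$W_vd <- gr$W_vd + drop(crossprod(cc$D2, csb))
  rsb <- rowSums(dbeta)  # identically zero by softmax shift-invariance
  gr$W_ve <- gr$W_ve + drop(crossprod(cc$Ve, rsb))
  dVe <- dVe + tcrossprod(rsb, params$W_ve)
  gr$demo_table[prep$d_idx[1L], ] <- gr$demo_table[prep$d_idx[1L], ] + dD2[1L, ]
  gr$demo_table[prep$d_idx[2L], ] <- gr$demo_table[prep$d_idx[2L], ] + dD2[2L, ]

  # value/event combination
  real <- prep$is_real
  dE <- matrix(0, n, ncol(dVe))
  if (any(real)) {
    dVe_r <- dVe[real, , drop = FALSE]
    gr$W_v <- gr$W_v + crossprod(cc$Vev[real, , drop = FALSE], dVe_r)
    gr$W_e <- gr$W_e + crossprod(cc$E[real, , drop = FALSE], dVe_r)
    gr$b_e <- gr$b_e + colSums(dVe_r)
    dE[real, ] <- tcrossprod(dVe_r, params$W_e)
    if (!variant$use_value_embedding) {
      dVev <- tcrossprod(dVe_r, params$W_v)
      gr$w_val <- gr$w_val + drop(crossprod(dVev, prep$s[real]))
      gr$b_val <- gr$b_val + colSums(dVev)
    }
  }
  if (any(!real)) dE[!real, ] <- dVe[!real, , drop = FALSE]
  acc <- rowsum(dE, prep$var_idx)
  rows <- as.integer(rownames(acc))
  gr$event_table[rows, ] <- gr$event_table[rows, , drop = FALSE] + acc
  gr
}

#' Forward pass for one patient
#'
#' Composes the embedding module, self-attention, pattern attention and
#' the risk head for a single (already windowed) patient, returning the
#' full attention trace used by the interpretability module: the
#' self-attention matrix `alpha` (rows sum to 1), the pattern weights
#' `gamma` (sum to 1), the pattern vectors `P`, the pooled
#' representation `h` and the risk `y`. The computation contains no
#' order-dependent operator, so permuting events (with their time
#' deltas) leaves the output unchanged.
#'
#' @param patient A [new_patient()] with a non-empty (windowed) event
#'   stream.
#' @param model A trained or freshly constructed [pave_model()].
#' @return A list of class `pave_trace` with elements `y`, `alpha`,
#'   `gamma`, `P`, `h`, and `events` (the event data frame with its
#'   `t_delta` column, indexing the rows of `alpha`).
#' @export
pave_forward <- function(patient, model) {
  stopifnot(inherits(model, "pave_model"))
  prep <- prepare_patient(patient, model$variables, model$norm,
                          model$embed_config, model$variant)
  fwd <- pave_fwd(prep, model$params, model$variant)
  ev <- prep$events
  ev$t_delta <- prep$deltas
  structure(list(y = fwd$y, alpha = fwd$alpha, gamma = fwd$gamma,
                 P = fwd$P, h = fwd$h, events = ev,
                 patient_id = patient$patient_id, label = patient$label),
            class = "pave_trace")
}

#' Construct an untrained model
#'
#' Bundles seeded parameters, the embedding configuration, the variant
#' flags and normalisation statistics into a model object; [train_pave()]
#' does this internally, but an untrained model is useful for
#' architecture-level checks (conservation laws, permutation
#' invariance).
#'
#' @param cohort A [new_cohort()] whose (windowed) patients provide the
#'   vocabulary and normalisation statistics.
#' @param k Embedding dimension.
#' @param seed Seed for parameter initialisation.
#' @param variant A [model_variant()].
#' @param j_base Sinusoid index origin, see [embedding_config()].
#' @return A list of class `pave_model`.
#' @export
pave_model <- function(cohort, k = 32L, seed = 1L,
                       variant = model_variant(), j_base = 0L) {
  wc <- window_cohort(cohort, quiet = TRUE)
  norm <- fit_normalization(wc$patients, wc$variables)
  structure(
    list(params = init_pave_params(names(wc$variables), k, seed),
         embed_config = embedding_config(k = k, t_m = norm$t_m, j_base = j_base),
         variant = variant, norm = norm, variables = wc$variables,
         history = NULL),
    class = "pave_model")
}

#' @export
print.pave_model <- function(x, ...) {
  cat(sprintf("<pave_model> variant %s, k = %d, t_m = %.1f h, %d variables%s\n",
              variant_name(x$variant), x$embed_config$k, x$embed_config$t_m,
              length(x$variables),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}
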