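# Continuous sinusoidal embeddings for event times and values, plus the
# demographic attention and the fusion layer producing per-event vectors.
#
# Only observed measurements are ever embedded: there is no imputation
# path in this module, which is the point of the value-embedding design.

#' Embedding configuration
#'
#' @param k Embedding dimension; even, at least 2. Desk-scale default is
#'   32 (512 is the reference scale).
#' @param t_m Maximum time interval in hours. Deltas above `t_m` are
#'   clamped; in a trained model `t_m` is estimated from the training
#'   split and frozen.
#' @param j_base Index origin for the sinusoid dimension index `j`
#'   (0 or 1). With `j_base = 0` dimension 0 is identically
#'   `sin(0) = 0`, the usual transformer convention.
#' @return A list of class `pave_embedding_config`.
#' @export
embedding_config <- function(k = 32L, t_m = 48, j_base = 0L) {
  k <- as.integer(k)
  if (k < 2L || k %% 2L != 0L) stopf("k must be an even integer >= 2")
  if (!is.finite(t_m) || t_m <= 0) stopf("t_m must be > 0")
  if (!j_base %in% c(0L, 1L)) stopf("j_base must be 0 or 1")
  structure(list(k = k, t_m = as.numeric(t_m), j_base = as.integer(j_base)),
            class = "pave_embedding_config")
}

# shared sinusoidal map: row per x, column per dimension j.
# argument is x * j / (x_max * k); even j -> sin, odd j -> cos.
sinusoid_embed <- function(x, x_max, k, j_base = 0L) {
  j <- j_base + seq_len(k) - 1L
  arg <- outer(x / (x_max * k), j)
  out <- arg
  even <- j %% 2L == 0L
  out[, even] <- sin(arg[, even, drop = FALSE])
  out[, !even] <- cos(arg[, !even, drop = FALSE])
  out
}

#' Sinusoidal time embedding
#'
#' Maps a time interval `t` (hours since the event, relative to the most
#' recent event in the window) to a `k`-vector whose dimension `j` is
#' `sin(t * j / (t_m * k))` for even `j` and `cos` of the same argument
#' for odd `j`. All entries lie in `[-1, 1]`, and the argument stays in
#' `[0, 1)` for `t <= t_m`, so the embedding is injective in `t`.
#'
#' @param t Numeric vector of non-negative intervals in hours. Values
#'   above `t_m` are clamped with a warning.
#' @param config An [embedding_config()].
#' @return A `length(t) x k` matrix (a plain vector if `t` is scalar).
#' @examples
#' time_embed(0, embedding_config(k = 4, t_m = 48))  # 0 1 0 1
#' @export
time_embed <- function(t, config) {
  stopifnot(inherits(config, "pave_embedding_config"))
  if (any(t < 0)) stopf("time intervals must be >= 0")
  if (any(t > config$t_m)) {
    warnf("time_embed: %d interval(s) above t_m = %g clamped",
          sum(t > config$t_m), config$t_m)
    t <- pmin(t, config$t_m)
  }
  out <- sinusoid_embed(t, config$t_m, config$k, config$j_base)
  if (length(t) == 1L) drop(out) else out
}

#' Sinusoidal value embedding
#'
#' Embeds a numeric measurement exactly like [time_embed()] after
#' min-max normalising it with the variable's range: dimension `j` is
#' `sin((v - v_min) * j / ((v_max - v_min) * k))` for even `j`, `cos`
#' for odd `j`. Because the formula depends only on the normalised
#' value, two variables measured at the same relative position of their
#' ranges share an embedding. Values outside `[v_min, v_max]` are
#' clamped.
#'
#' @param value Numeric vector of observed values.
#' @param spec A real-valued [variable_spec()] (or any list with
#'   `v_min`/`v_max`, e.g. train-split normalisation statistics).
#' @param config An [embedding_config()].
#' @return A `length(value) x k` matrix (vector if scalar input).
#' @export
value_embed <- function(value, spec, config) {
  stopifnot(inherits(config, "pave_embedding_config"))
  if (identical(spec$kind %||% "real", "boolean"))
    stopf("value_embed applies to real variables only")
  rng <- spec$v_max - spec$v_min
  if (!is.finite(rng) || rng <= 0)
    stopf("value_embed: need v_min < v_max")
  v <- clamp(value, spec$v_min, spec$v_max) - spec$v_min
  out <- sinusoid_embed(v, rng, config$k, config$j_base)
  if (length(value) == 1L) drop(out) else out
}

# ---- learnable parameters ----------------------------------------------

demo_rows <- function() c(paste0("gender:", PAVE_GENDERS),
                          paste0("age:", PAVE_AGE_GROUPS))

init_mat <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -1 / sqrt(k), 1 / sqrt(k)), nr, nc)
}

#' Initialise all learnable parameters
#'
#' Weight matrices and vectors are drawn uniform on
#' `(-1/sqrt(k), 1/sqrt(k))` (fan-in scaling), biases start at zero, and
#' the draw is seeded for reproducibility. Covers the event/demographic
#' embedding tables, the value/event combination layer, demographic
#' attention, the event fusion layer, the self-attention
#' query/key/value projections, the pattern attention, the risk head,
#' and the scalar value projection used by the no-value-embedding
#' ablation.
#'
#' @param variable_ids Character vector: vocabulary of event types.
#' @param k Embedding dimension.
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_pave_params <- function(variable_ids, k, seed = 1L) {
  k <- as.integer(k)
  dr <- demo_rows()
  with_seed(seed, {
    p <- list(
      event_table = init_mat(length(variable_ids), k, k),
      W_v = init_mat(k, k, k), W_e = init_mat(k, k, k), b_e = numeric(k),
      demo_table = init_mat(length(dr), k, k),
      W_vd = stats::runif(k, -1 / sqrt(k), 1 / sqrt(k)),
      W_ve = stats::runif(k, -1 / sqrt(k), 1 / sqrt(k)),
      W_qe = init_mat(k, k, k), W_qt = init_mat(k, k, k),
      W_qd = init_mat(k, k, k), b_q = numeric(k),
      W_Q = init_mat(k, k, k), b_Q = numeric(k),
      W_K = init_mat(k, k, k), b_K = numeric(k),
      W_V = init_mat(k, k, k), b_V = numeric(k),
      W_p = stats::runif(k, -1 / sqrt(k), 1 / sqrt(k)), b_p = 0,
      W_h = stats::runif(k, -1 / sqrt(k), 1 / sqrt(k)), b_h = 0,
      w_val = stats::runif(k, -1 / sqrt(k), 1 / sqrt(k)), b_val = numeric(k))
    rownames(p$event_table) <- variable_ids
    rownames(p$demo_table) <- dr
    p
  })
}

#' Combine value and event-type embeddings
#'
#' For real variables the combined event embedding is the linear fusion
#' `v_ev %*% W_v + v_ee %*% W_e + b_e` of the sinusoidal value embedding
#' and the event-type table row. Boolean events bypass the fusion and
#' use the raw event-table row directly (a boolean event carries no
#' value information beyond its presence).
#'
#' @param event One-row event data frame (or list) with `variable_id`
#'   and `value`.
#' @param spec The event's [variable_spec()].
#' @param params Parameters from [init_pave_params()].
#' @param config An [embedding_config()].
#' @return A `k`-vector.
#' @export
combine_event_value <- function(event, spec, params, config) {
  id <- event$variable_id
  if (!id %in% rownames(params$event_table))
    stopf("variable '%s' not in event table", id)
  v_ee <- params$event_table[id, ]
  if (spec$kind == "boolean") return(v_ee)
  v_ev <- value_embed(event$value, spec, config)
  drop(v_ev %*% params$W_v + v_ee %*% params$W_e) + params$b_e
}

#' Demographic attention
#'
#' Scores each of the patient's demographic attributes (gender row and
#' age-group row of the demographic table) with
#' `beta_j = v_j_d . W_vd + v_e . W_ve`, softmaxes the scores into
#' weights `alpha`, and returns the weighted sum of the attribute
#' embeddings together with the weights. Note that the `v_e . W_ve` term
#' is shared by all attributes, so it shifts every score equally and
#' cancels inside the softmax; it is kept for fidelity to the scoring
#' form.
#'
#' @param demographics List with `gender` and `age_group`.
#' @param v_e Combined event embedding (`k`-vector).
#' @param params Parameters from [init_pave_params()].
#' @return List with `v_da` (`k`-vector) and `weights` (one weight per
#'   attribute, non-negative, summing to 1).
#' @export
demographic_attend <- function(demographics, v_e, params) {
  rows <- c(paste0("gender:", demographics$gender),
            paste0("age:", demographics$age_group))
  D <- params$demo_table[rows, , drop = FALSE]
  beta <- drop(D %*% params$W_vd) + sum(v_e * params$W_ve)
  alpha <- softmax_vec(beta)
  list(v_da = drop(crossprod(D, alpha)), weights = alpha)
}

#' Embed one event
#'
#' Full per-event embedding: sinusoidal time embedding of the recency
#' delta, value/event combination, demographic attention, and the fusion
#' `q = v_e W_qe + v_t W_qt + v_da W_qd + b_q`. All intermediate vectors
#' are returned.
#'
#' @param event One-row event data frame (or list) with `variable_id`
#'   and `value`.
#' @param t_delta Recency delta of the event in hours (see
#'   [compute_time_deltas()]).
#' @param demographics List with `gender` and `age_group`.
#' @param spec The event's [variable_spec()].
#' @param params Parameters from [init_pave_params()].
#' @param config An [embedding_config()].
#' @return List of class `pave_event_embedding` with elements `v_t`,
#'   `v_ev` (NULL for boolean events), `v_e`, `v_da`, `demo_weights`,
#'   and the fused `q`.
#' @export
embed_event <- function(event, t_delta, demographics, spec, params, config) {
  v_t <- time_embed(t_delta, config)
  v_ev <- if (spec$kind == "real") value_embed(event$value, spec, config) else NULL
  v_e <- combine_event_value(event, spec, params, config)
  da <- demographic_attend(demographics, v_e, params)
  q <- drop(v_e %*% params$W_qe + v_t %*% params$W_qt +
              da$v_da %*% params$W_qd) + params$b_q
  structure(list(v_t = v_t, v_ev = v_ev, v_e = v_e, v_da = da$v_da,
                 demo_weights = da$weights, q = q),
            class = "pave_event_embedding")
}
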