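# Fixtures are built in code; independent oracles used to freeze
# expected values live here too.

tiny_vars <- function() {
  as_dict <- function(...) {
    specs <- list(...)
    names(specs) <- vapply(specs, `[[`, "", "variable_id")
    specs
  }
  as_dict(
    variable_spec("heart_rate", "real", 20, 220, 60, 100, "Heart rate"),
    variable_spec("temperature", "real", 32, 42.5, 36, 38, "Temperature"),
    variable_spec("antibiotic", "boolean", display_name = "Antibiotic given"))
}

empty_events_df <- function() {
  data.frame(variable_id = character(), value = numeric(),
             time = numeric(), collection_id = integer(),
             stringsAsFactors = FALSE)
}

tiny_events <- function(var, value, time, coll = seq_along(time)) {
  data.frame(variable_id = var, value = value, time = time,
             collection_id = coll, stringsAsFactors = FALSE)
}

tiny_patient <- function(id = "p1", gender = "male", age_group = "60-69",
                         events = tiny_events("heart_rate", c(80, 90, 120),
                                              c(-30, -20, -12)),
                         label = 1L, anchor = 0) {
  new_patient(id, gender, age_group, events, label, anchor)
}

tiny_cohort <- function(patients = list(tiny_patient()),
                        vars = tiny_vars(), obs = 48, holdoff = 10) {
  new_cohort(patients, vars, obs, holdoff)
}

# a small simulated cohort shared by several tests (built once)
small_sim_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(synthetic_spec(n_cases = 10, seed = 4242))
    cache
  }
})

# independent per-dimension scalar-loop oracle for the sinusoidal
# embeddings: evaluates the piecewise sin/cos definition one dimension
# at a time
oracle_sinusoid <- function(x, x_max, k, j_base = 0L) {
  out <- numeric(k)
  for (d in seq_len(k)) {
    j <- j_base + d - 1L
    arg <- x * j / (x_max * k)
    out[d] <- if (j %% 2L == 0L) sin(arg) else cos(arg)
  }
  out
}

# brute-force double-loop oracle for self-attention
oracle_self_attend <- function(q, params) {
  n <- nrow(q)
  k <- ncol(q)
  Q <- matrix(0, n, k); K <- matrix(0, n, k); V <- matrix(0, n, k)
  for (i in seq_len(n)) {
    Q[i, ] <- q[i, ] %*% params$W_Q + params$b_Q
    K[i, ] <- q[i, ] %*% params$W_K + params$b_K
    V[i, ] <- q[i, ] %*% params$W_V + params$b_V
  }
  beta <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) beta[i, j] <- sum(Q[i, ] * K[j, ])
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- exp(beta[i, ] - max(beta[i, ]))
    alpha[i, ] <- e / sum(e)
  }
  P <- matrix(0, n, k)
  for (i in seq_len(n)) {
    s <- V[i, ]
    for (j in seq_len(n)) s <- s + alpha[i, j] * V[j, ]
    P[i, ] <- s
  }
  list(P = P, alpha = alpha)
}

# all-pairs concordance AUROC oracle (midrank ties)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
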