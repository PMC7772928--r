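# Training loop (Adam on the binary cross-entropy), rank-based AUROC,
# stratified splits, rotating 7/1/2 tenfold cross-validation and the
# ablation runner.

#' Training configuration
#'
#' Desk-scale defaults (embedding dimension 32, 20 epochs, batch 8,
#' learning rate 3e-3) are sized for cohorts of a few hundred patients,
#' where larger steps and more frequent updates per epoch compensate
#' for the small number of gradient steps;
#' the reference-scale settings for cohorts of tens of thousands are
#' `k = 512`, 50 epochs, batch 64, learning rate 1e-4.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Patients per mini-batch.
#' @param epochs Number of passes over the training data.
#' @param k Embedding dimension.
#' @param seed Seed for parameter initialisation and batch shuffling.
#' @param variant A [model_variant()].
#' @param j_base Sinusoid index origin, see [embedding_config()].
#' @return A list of class `pave_train_config`.
#' @export
train_config <- function(learning_rate = 3e-3, batch_size = 8L,
                         epochs = 20L, k = 32L, seed = 1L,
                         variant = model_variant(), j_base = 0L) {
  if (learning_rate < 0) stopf("learning_rate must be >= 0")
  if (epochs < 1) stopf("epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k = as.integer(k),
                 seed = as.integer(seed), variant = variant,
                 j_base = as.integer(j_base)),
            class = "pave_train_config")
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, gr, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train a pattern-attention model
#'
#' Minimises the binary cross-entropy by mini-batch Adam. Patients are
#' windowed with the cohort's stored geometry (empty windows dropped),
#' normalisation statistics and the maximum time delta are fitted on the
#' training cohort only, and each patient's sequence is processed at its
#' natural length, so every softmax normalises over real events only.
#' When a validation cohort is supplied, validation AUROC is tracked per
#' epoch and the returned model carries the parameters of the best
#' validation epoch.
#'
#' Attention models trained on interaction-dominated signals
#' occasionally stall at the base-rate predictor or at a partial
#' solution from an unlucky initialisation. When a validation cohort is
#' available the trainer therefore restarts (up to `max_restarts` extra
#' attempts) until an attempt looks converged on validation data — best
#' validation AUROC at least `restart_val_auroc` *and* validation
#' cross-entropy at the selected checkpoint at most `restart_val_loss`
#' (a fully learned solution is both discriminative and well
#' calibrated, while a lucky partial solution rarely is) — re-initialising
#' each attempt with a fresh derived seed and a moderately jittered
#' learning rate. The attempt with the highest validation AUROC
#' (validation loss breaking ties) is returned; test data never
#' influence the selection.
#'
#' @param cohort Training [new_cohort()]; must contain both classes.
#' @param config A [train_config()].
#' @param validation Optional validation cohort for checkpoint
#'   selection.
#' @param quiet Suppress per-epoch progress messages.
#' @param max_restarts Maximum number of re-initialisations when
#'   training stalls (requires `validation`).
#' @param restart_val_auroc,restart_val_loss Convergence bars on
#'   validation AUROC and validation cross-entropy; an attempt missing
#'   either counts as stalled.
#' @return A `pave_model` with a `history` data frame (epoch, mean
#'   training loss, validation AUROC when available).
#' @export
train_pave <- function(cohort, config = train_config(), validation = NULL,
                       quiet = TRUE, max_restarts = 6L,
                       restart_val_auroc = 0.93, restart_val_loss = 0.35) {
  fit <- train_pave_once(cohort, config, validation, quiet)
  if (is.null(validation) || max_restarts < 1L) return(fit)
  better <- function(a, b) {
    a$val_auroc > b$val_auroc ||
      (a$val_auroc == b$val_auroc && a$val_loss < b$val_loss)
  }
  converged <- function(f)
    f$val_auroc >= restart_val_auroc && f$val_loss <= restart_val_loss
  best <- fit
  attempt <- 0L
  # moderate rates only: large steps reliably overshoot on this problem
  lr_jitter <- c(2 / 3, 1, 2 / 3, 1, 2 / 3, 1)
  while (!converged(best) && attempt < max_restarts) {
    attempt <- attempt + 1L
    cfg <- config
    cfg$seed <- config$seed + 1000L * attempt
    cfg$learning_rate <- config$learning_rate *
      lr_jitter[(attempt - 1L) %% length(lr_jitter) + 1L]
    if (!quiet) message(sprintf("restart %d (val AUROC %.3f, val loss %.3f)",
                                attempt, best$val_auroc, best$val_loss))
    fit <- train_pave_once(cohort, cfg, validation, quiet)
    if (better(fit, best)) best <- fit
  }
  best
}

train_pave_once <- function(cohort, config, validation = NULL, quiet = TRUE) {
  stopifnot(inherits(cohort, "pave_cohort"),
            inherits(config, "pave_train_config"))
  wc <- window_cohort(cohort, quiet = quiet)
  labs <- vapply(wc$patients, `[[`, 0L, "label")
  if (length(unique(labs)) < 2L)
    stopf("training data must contain both classes")
  norm <- fit_normalization(wc$patients, wc$variables)
  econf <- embedding_config(k = config$k, t_m = norm$t_m, j_base = config$j_base)
  variant <- config$variant
  params <- init_pave_params(names(wc$variables), config$k, config$seed)
  preps <- lapply(wc$patients, prepare_patient, variables = wc$variables,
                  norm = norm, config = econf, variant = variant)

  val_preps <- NULL
  if (!is.null(validation)) {
    wv <- window_cohort(validation, quiet = quiet)
    val_preps <- lapply(wv$patients, prepare_patient,
                        variables = wc$variables, norm = norm,
                        config = econf, variant = variant)
  }

  npat <- length(preps)
  state <- adam_init(params)
  best <- list(auroc = -Inf, loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auroc = numeric())
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(npat)
      total_loss <- 0
      for (start in seq(1L, npat, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, npat)]
        gr <- zero_grads(params)
        scale <- 1 / length(idx)
        for (i in idx) {
          fwd <- pave_fwd(preps[[i]], params, variant, want_cache = TRUE)
          total_loss <- total_loss + bce_loss(fwd$y, preps[[i]]$label)
          gr <- pave_bwd(fwd, params, variant, gr, scale)
        }
        if (config$learning_rate > 0) {
          upd <- adam_step(params, gr, state, config$learning_rate)
          params <- upd$params
          state <- upd$state
        }
      }
      val_auroc <- NA_real_
      if (!is.null(val_preps)) {
        vy <- vapply(val_preps, function(pp) pave_fwd(pp, params, variant)$y, 0)
        vl <- vapply(val_preps, `[[`, 0L, "label")
        val_auroc <- auroc_midrank(vy, vl)
        vloss <- mean(bce_loss(vy, vl))
        if (val_auroc > best$auroc ||
            (val_auroc == best$auroc && vloss < best$loss))
          best <- list(auroc = val_auroc, loss = vloss, params = params,
                       epoch = ep)
      }
      history <- rbind(history, data.frame(epoch = ep, loss = total_loss / npat,
                                           val_auroc = val_auroc))
      if (!quiet)
        message(sprintf("epoch %d: loss %.4f%s", ep, total_loss / npat,
                        if (is.na(val_auroc)) "" else
                          sprintf(", val AUROC %.3f", val_auroc)))
    }
  })
  final_params <- if (!is.null(val_preps) && best$epoch > 0L) best$params else params
  structure(list(params = final_params, embed_config = econf,
                 variant = variant, norm = norm, variables = wc$variables,
                 history = history,
                 best_epoch = if (!is.null(val_preps)) best$epoch else NA_integer_,
                 val_auroc = if (!is.null(val_preps)) best$auroc else NA_real_,
                 val_loss = if (!is.null(val_preps)) best$loss else NA_real_,
                 train_config = config),
            class = "pave_model")
}

# midrank (Wilcoxon) AUROC
auroc_midrank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stopf("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predict risks for a cohort
#'
#' @param object A trained [pave_model()].
#' @param cohort A [new_cohort()]; patients are windowed with the
#'   cohort's geometry and empty windows dropped.
#' @param ... Unused.
#' @return Data frame with `patient_id`, `label`, `y`.
#' @export
predict.pave_model <- function(object, cohort, ...) {
  wc <- window_cohort(cohort, quiet = TRUE)
  y <- vapply(wc$patients, function(p) pave_forward(p, object)$y, 0)
  data.frame(patient_id = vapply(wc$patients, `[[`, "", "patient_id"),
             label = vapply(wc$patients, `[[`, 0L, "label"),
             y = y, stringsAsFactors = FALSE)
}

#' Rank-based AUROC of a model on a cohort
#'
#' Area under the ROC curve computed from midranks (ties shared), i.e.
#' the probability that a random case outscores a random control.
#'
#' @param model A trained [pave_model()].
#' @param cohort A [new_cohort()] containing both classes.
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(model, cohort) {
  pr <- predict(model, cohort)
  auroc_midrank(pr$y, pr$label)
}

#' Stratified cohort split
#'
#' Splits a cohort into named sub-cohorts with the given proportions,
#' stratified by label so every split keeps both classes, using a seeded
#' shuffle.
#'
#' @param cohort A [new_cohort()].
#' @param props Named numeric vector of proportions summing to 1, e.g.
#'   `c(train = 0.7, val = 0.1, test = 0.2)`.
#' @param seed Integer seed.
#' @return Named list of cohorts.
#' @export
split_cohort <- function(cohort, props = c(train = 0.7, val = 0.1, test = 0.2),
                         seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-8, !is.null(names(props)))
  labs <- vapply(cohort$patients, `[[`, 0L, "label")
  assign_split <- function(idx) {
    n <- length(idx)
    sizes <- floor(props * n)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    rep(names(props), times = sizes)
  }
  out <- rep(NA_character_, length(labs))
  with_seed(seed, {
    for (lv in unique(labs)) {
      idx <- sample(which(labs == lv))
      out[idx] <- assign_split(idx)
    }
  })
  lapply(stats::setNames(names(props), names(props)), function(nm) {
    cohort2 <- cohort
    cohort2$patients <- cohort$patients[out == nm]
    cohort2
  })
}

#' Fold assignment for rotating 7/1/2 cross-validation
#'
#' Partitions patients into 10 label-stratified sets (seeded; sets
#' within one of equal size per class) and builds 10 folds where fold
#' `f` trains on sets `f..f+6`, validates on set `f+7` and tests on sets
#' `f+8, f+9` (indices mod 10). Every set — hence every patient — is
#' used for testing exactly twice across the folds.
#'
#' @param n_patients Number of patients.
#' @param labels Integer labels (for stratification).
#' @param seed Integer seed.
#' @return List with `set` (set index 1..10 per patient) and `folds`
#'   (list of 10 lists with `train`, `val`, `test` set indices).
#' @export
cv_folds <- function(n_patients, labels, seed = 1L) {
  nsets <- 10L
  set_of <- integer(n_patients)
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      set_of[idx] <- rep_len(seq_len(nsets), length(idx))
    }
  })
  folds <- lapply(seq_len(nsets), function(f) {
    rot <- ((f - 1L + 0L:(nsets - 1L)) %% nsets) + 1L
    list(train = rot[1:7], val = rot[8], test = rot[9:10])
  })
  list(set = set_of, folds = folds)
}

subset_cohort <- function(cohort, keep) {
  cohort$patients <- cohort$patients[keep]
  cohort
}

#' Tenfold cross-validation with a rotating 7/1/2 split
#'
#' Runs [train_pave()] on each of the 10 folds from [cv_folds()]
#' (7 sets train, 1 validation, 2 test), refitting normalisation
#' statistics inside each fold's training split, and reports the
#' per-fold test AUROCs with their mean and standard deviation.
#'
#' @param cohort A [new_cohort()] with at least 10 patients per class.
#' @param config A [train_config()].
#' @param quiet Suppress progress messages.
#' @param ... Passed on to [train_pave()] (e.g. `max_restarts`).
#' @return A list of class `pave_cv` with `fold_aurocs`, `mean`, `sd`.
#' @export
crossval_pave <- function(cohort, config = train_config(), quiet = TRUE, ...) {
  labs <- vapply(cohort$patients, `[[`, 0L, "label")
  if (min(table(labs)) < 10L)
    stopf("crossval needs at least 10 patients per class")
  cv <- cv_folds(length(labs), labs, seed = config$seed)
  aurocs <- vapply(seq_along(cv$folds), function(f) {
    fold <- cv$folds[[f]]
    fit <- train_pave(subset_cohort(cohort, cv$set %in% fold$train), config,
                      validation = subset_cohort(cohort, cv$set %in% fold$val),
                      quiet = TRUE, ...)
    a <- evaluate_auroc(fit, subset_cohort(cohort, cv$set %in% fold$test))
    if (!quiet) message(sprintf("fold %d: test AUROC %.3f", f, a))
    a
  }, 0)
  structure(list(fold_aurocs = aurocs, mean = mean(aurocs),
                 sd = stats::sd(aurocs)),
            class = "pave_cv")
}

#' @export
print.pave_cv <- function(x, ...) {
  cat(sprintf("<pave_cv> AUROC %.3f +/- %.3f over %d folds\n",
              x$mean, x$sd, length(x$fold_aurocs)))
  invisible(x)
}

#' Ablation comparison
#'
#' Cross-validates the full model and the two ablations (no time
#' embedding; no value embedding) under identical folds and seeds.
#'
#' @param cohort A [new_cohort()].
#' @param config A [train_config()]; its `variant` is overridden per
#'   run.
#' @param quiet Suppress progress messages.
#' @param ... Passed on to [train_pave()] via [crossval_pave()].
#' @return Data frame with one row per variant: `variant`, `mean_auroc`,
#'   `sd_auroc`.
#' @export
run_ablation <- function(cohort, config = train_config(), quiet = TRUE, ...) {
  variants <- list(
    PAVE = model_variant(TRUE, TRUE),
    `PAVE-T` = model_variant(FALSE, TRUE),
    `PAVE-V` = model_variant(TRUE, FALSE))
  rows <- lapply(names(variants), function(nm) {
    cfg <- config
    cfg$variant <- variants[[nm]]
    cv <- crossval_pave(cohort, cfg, quiet = quiet, ...)
    data.frame(variant = nm, mean_auroc = cv$mean, sd_auroc = cv$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save or load a model checkpoint
#'
#' Checkpoints bundle the parameter tensors, embedding configuration,
#' variant flags, normalisation statistics and vocabulary, with a format
#' version tag, as an RDS container.
#'
#' @param model A `pave_model`.
#' @param path Destination path.
#' @return `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pave_model"))
  saveRDS(list(format = "pave-checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "pave-checkpoint"))
    stopf("not a model checkpoint: %s", path)
  x$model
}
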