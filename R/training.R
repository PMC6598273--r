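# Activity-model training: concentration-based labelling, mismatch-weighted
# downsampling with repeats, Random-Forest training, importance averaging,
# backward feature selection by OOB error, and final model selection.

#' Label sites by minimal active concentration
#'
#' A site is active iff its minimal detection concentration is at most
#' `threshold_nM`; sites never detected (`NA`) are inactive.
#'
#' @param sites Tibble with a `min_active_concentration` column (nM).
#' @param threshold_nM Concentration threshold, default 64 nM.
#' @return `sites` with the `label` column set.
#' @export
label_by_concentration <- function(sites, threshold_nM = 64) {
  dplyr::mutate(sites, label = dplyr::if_else(
    !is.na(.data$min_active_concentration) &
      .data$min_active_concentration <= threshold_nM,
    "active", "inactive"))
}

#' Mismatch-weighted downsampling of inactive sites
#'
#' Builds `n_repeats` balanced datasets: each keeps all active sites and
#' samples (without replacement, independently per repeat) inactive sites
#' whose per-mismatch-count histogram equals the actives' histogram. If a
#' pool bin cannot cover the demand it is filled to availability and the
#' shortfall reported with a warning.
#'
#' @param sites Labelled tibble with `label` and `n_mismatches` columns.
#' @param n_repeats Number of balanced datasets, default 10.
#' @param seed RNG seed; repeat `r` uses a sub-seed derived from it.
#' @return A tibble with columns `repeat_index` and `data` (list of
#'   balanced tibbles, each with an `.inactive_row` id column on sampled
#'   rows); shortfalls, if any, are attached as attribute `shortfall`.
#' @export
sample_inactive <- function(sites, n_repeats = 10L, seed = 1L) {
  act <- sites[sites$label == "active", , drop = FALSE]
  pool <- sites[sites$label == "inactive", , drop = FALSE]
  if (nrow(act) == 0L) abort("no active sites to balance against")
  demand <- table(act$n_mismatches)
  shortfalls <- list()
  reps <- lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      picked <- integer(0)
      for (b in names(demand)) {
        avail <- which(pool$n_mismatches == as.integer(b))
        want <- demand[[b]]
        if (length(avail) < want) {
          shortfalls[[length(shortfalls) + 1L]] <<- tibble::tibble(
            repeat_index = r, n_mismatches = as.integer(b),
            demanded = as.integer(want), sampled = length(avail))
          warn(sprintf("repeat %d: inactive pool has %d site(s) with %s mismatches, %d demanded",
                       r, length(avail), b, want))
          picked <- c(picked, avail)
        } else {
          picked <- c(picked, avail[sample.int(length(avail), want)])
        }
      }
      ina <- pool[sort(picked), , drop = FALSE]
      ina$.inactive_row <- sort(picked)
      act$.inactive_row <- NA_integer_
      dplyr::bind_rows(act, ina)
    })
  })
  out <- tibble::tibble(repeat_index = seq_len(n_repeats), data = reps)
  attr(out, "shortfall") <- dplyr::bind_rows(shortfalls)
  out
}

fit_forest <- function(X, y, ntree, mtry, seed) {
  with_seed(seed, {
    randomForest::randomForest(
      x = as.data.frame(X), y = y, ntree = ntree,
      mtry = if (is.null(mtry)) max(1L, floor(sqrt(ncol(X)))) else mtry,
      importance = TRUE)
  })
}

oob_error <- function(forest) {
  unname(forest$err.rate[nrow(forest$err.rate), "OOB"])
}

prepare_xy <- function(data, features) {
  X <- extract_features(data$on_target, data$off_target)[, features,
                                                         drop = FALSE]
  y <- factor(data$label, levels = c("inactive", "active"))
  if (length(unique(data$label)) < 2L) {
    abort("training data must contain both classes")
  }
  list(X = X, y = y)
}

#' Train one Random Forest per balanced dataset
#'
#' @param repeats Output of [sample_inactive()].
#' @param features Feature names to train on; default the full schema.
#' @param ntree Trees per forest (default 500).
#' @param mtry Features per split; default `floor(sqrt(p))`.
#' @param seed RNG seed; repeat `r` gets a derived sub-seed.
#' @return A tibble with `repeat_index`, `forest` (list), `oob` (final OOB
#'   error), `importance` (list of tibbles `feature`, `importance` using
#'   mean decrease in Gini impurity).
#' @export
train_models <- function(repeats, features = feature_schema(), ntree = 500L,
                         mtry = NULL, seed = 1L) {
  rows <- lapply(seq_len(nrow(repeats)), function(i) {
    d <- prepare_xy(repeats$data[[i]], features)
    f <- fit_forest(d$X, d$y, ntree, mtry,
                    derive_seed(seed, 100L + repeats$repeat_index[[i]]))
    imp <- randomForest::importance(f, type = 2L)
    tibble::tibble(
      repeat_index = repeats$repeat_index[[i]], forest = list(f),
      oob = oob_error(f),
      importance = list(tibble::tibble(feature = rownames(imp),
                                       importance = unname(imp[, 1L]))))
  })
  dplyr::bind_rows(rows)
}

#' Average feature importance across repeats
#'
#' @param models Output of [train_models()].
#' @return Tibble (`feature`, `mean_importance`) in descending order of
#'   importance, ties broken alphabetically by feature name.
#' @export
average_importance <- function(models) {
  if (nrow(models) == 0L) abort("need at least one trained model")
  all <- dplyr::bind_rows(models$importance)
  out <- dplyr::summarise(dplyr::group_by(all, .data$feature),
                          mean_importance = mean(.data$importance),
                          .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$mean_importance), .data$feature)
}

#' Backward feature selection by OOB error
#'
#' Starting from the full feature set, repeatedly removes the least
#' important remaining feature (per the supplied averaged-importance
#' ranking), refits on one representative balanced dataset, and records the
#' OOB error. The selected set is the one with the lowest OOB error along
#' the curve; ties go to the smaller set.
#'
#' @param repeats Output of [sample_inactive()].
#' @param ranking Averaged-importance ranking from [average_importance()];
#'   must cover all schema features being considered.
#' @param representative Which repeat's dataset to refit on (default 1).
#' @param ntree Trees per refit.
#' @param seed RNG seed.
#' @return A list with `selected_features` (character) and `curve`, a
#'   tibble with one row per model fitted (`step` 0 = full set, then one
#'   per removal): `step`, `n_features`, `dropped_feature`, `oob`.
#' @export
backward_select <- function(repeats, ranking, representative = 1L,
                            ntree = 500L, seed = 1L) {
  feats <- ranking$feature  # most to least important
  data <- repeats$data[[which(repeats$repeat_index == representative)]]
  d <- prepare_xy(data, feats)
  steps <- vector("list", length(feats))
  current <- feats
  for (step in 0:(length(feats) - 1L)) {
    dropped <- NA_character_
    if (step > 0L) {
      dropped <- current[[length(current)]]  # least important remaining
      current <- current[-length(current)]
    }
    f <- fit_forest(d$X[, current, drop = FALSE], d$y, ntree, NULL,
                    derive_seed(seed, 500L + step))
    steps[[step + 1L]] <- tibble::tibble(step = step,
                                         n_features = length(current),
                                         dropped_feature = dropped,
                                         oob = oob_error(f))
  }
  curve <- dplyr::bind_rows(steps)
  # lowest OOB; ties resolved towards the smaller feature set
  best <- curve[curve$oob == min(curve$oob), , drop = FALSE]
  best_step <- max(best$step)
  list(selected_features = feats[seq_len(length(feats) - best_step)],
       curve = curve)
}

#' Fit the final activity model
#'
#' Refits every balanced dataset on the selected features and returns the
#' repeat with the lowest OOB error (ties: lowest repeat index), packaged
#' with its schema version, seeds and importance table.
#'
#' @param repeats Output of [sample_inactive()].
#' @param selected_features Feature names retained by [backward_select()].
#' @param ntree,mtry Forest hyperparameters.
#' @param seed RNG seed.
#' @param selection_curve Optional OOB curve to store for plotting.
#' @return An object of class `ot_model`: list with `forest`, `features`,
#'   `schema_version`, `repeat_index`, `oob`, `oob_all`, `ntree`, `seed`,
#'   `importance`, `selection_curve`.
#' @export
select_final_model <- function(repeats, selected_features, ntree = 500L,
                               mtry = NULL, seed = 1L,
                               selection_curve = NULL) {
  refits <- train_models(repeats, features = selected_features,
                         ntree = ntree, mtry = mtry, seed = seed)
  best <- which(refits$oob == min(refits$oob))[[1L]]
  structure(list(
    forest = refits$forest[[best]],
    features = selected_features,
    schema_version = "1",
    repeat_index = refits$repeat_index[[best]],
    oob = refits$oob[[best]],
    oob_all = setNames(refits$oob, refits$repeat_index),
    ntree = as.integer(ntree),
    seed = as.integer(seed),
    importance = refits$importance[[best]],
    selection_curve = selection_curve
  ), class = "ot_model")
}

#' @export
print.ot_model <- function(x, ...) {
  cat(sprintf(paste0("<ot_model> Random-Forest activity model\n",
                     "  features: %d (schema %s)\n",
                     "  trees: %d, repeat %d of %d, OOB error %.4f\n"),
              length(x$features), x$schema_version, x$ntree, x$repeat_index,
              length(x$oob_all), x$oob))
  invisible(x)
}

#' Save / load an activity model
#'
#' @param model An `ot_model`.
#' @param path File path (RDS).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ot_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ot_model")) abort("file does not contain an ot_model")
  m
}

#' Cross-validated AUC on a labelled table
#'
#' Stratified k-fold cross-validation of a forest on the given sites, with
#' the ROC AUC computed on pooled held-out predictions.
#'
#' @param sites Labelled tibble (`on_target`, `off_target`, `label`).
#' @param features Feature names to use.
#' @param nfolds Number of folds.
#' @param ntree Trees per fold model.
#' @param seed RNG seed.
#' @return A list with `auc` and the pooled `predictions` tibble.
#' @export
cv_auc <- function(sites, features = feature_schema(), nfolds = 5L,
                   ntree = 500L, seed = 1L) {
  d <- prepare_xy(sites, features)
  folds <- with_seed(derive_seed(seed, 77L), {
    f <- integer(nrow(sites))
    for (cl in levels(d$y)) {
      idx <- which(d$y == cl)
      f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    f
  })
  preds <- numeric(nrow(sites))
  for (k in seq_len(nfolds)) {
    test <- folds == k
    f <- fit_forest(d$X[!test, , drop = FALSE], d$y[!test], ntree, NULL,
                    derive_seed(seed, 600L + k))
    preds[test] <- predict(f, newdata = as.data.frame(d$X[test, , drop = FALSE]),
                           type = "prob")[, "active"]
  }
  roc <- pROC::roc(response = d$y, predictor = preds, levels = c("inactive", "active"),
                   direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)),
       predictions = tibble::tibble(label = as.character(d$y), prob = preds,
                                    fold = folds))
}

#' Out-of-bag AUC of a trained model
#'
#' AUC computed from the forest's out-of-bag votes on its own training
#' data.
#'
#' @param forest A `randomForest` fit.
#' @return Numeric AUC.
#' @export
oob_auc <- function(forest) {
  votes <- forest$votes[, "active"]
  roc <- pROC::roc(response = forest$y, predictor = as.numeric(votes),
                   levels = c("inactive", "active"), direction = "<",
                   quiet = TRUE)
  as.numeric(pROC::auc(roc))
}

#' Mean predicted activity per concentration tier
#'
#' Groups tiered test sites by their minimal active concentration and
#' reports the mean predicted probability per tier (never-detected sites
#' form the `NA` tier). Tiers absent from the data are omitted with a
#' message.
#'
#' @param model An `ot_model`.
#' @param sites Tibble with `on_target`, `off_target` and
#'   `min_active_concentration` columns.
#' @param tiers Expected tiers, used only to report omissions.
#' @return Tibble (`min_active_concentration`, `n`, `mean_prob`) ordered by
#'   concentration with the `NA` tier last.
#' @export
concentration_correlation <- function(model, sites,
                                      tiers = c(4, 16, 64, 256)) {
  prob <- predict_activity(model, extract_features(sites$on_target,
                                                   sites$off_target))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(sites, .prob = prob),
                    .data$min_active_concentration),
    n = dplyr::n(), mean_prob = mean(.data$.prob), .groups = "drop")
  missing <- setdiff(tiers, out$min_active_concentration)
  if (length(missing) > 0L) {
    inform(sprintf("concentration tier(s) %s not present in data; omitted",
                   paste(missing, collapse = ", ")))
  }
  dplyr::arrange(out, .data$min_active_concentration)
}

#' Run the full training pipeline on a labelled table
#'
#' Convenience wrapper: concentration labelling, mismatch-weighted
#' downsampling with repeats, training, importance averaging, backward
#' selection and final-model choice. Sites with non-canonical PAMs
#' (off-target PAM not NGG) are excluded by default.
#'
#' @param sites Labelled training tibble (see [sim_training_table()] for
#'   the layout).
#' @param n_repeats Balanced datasets to draw.
#' @param ntree Trees per forest.
#' @param canonical_pam_only Restrict to off-targets with an NGG PAM.
#' @param threshold_nM Concentration threshold for labelling.
#' @param seed RNG seed driving the whole pipeline.
#' @return The final `ot_model`, with `repeats`, `ranking` and the
#'   selection curve attached.
#' @export
train_activity_model <- function(sites, n_repeats = 10L, ntree = 500L,
                                 canonical_pam_only = TRUE,
                                 threshold_nM = 64, seed = 1L) {
  if (canonical_pam_only) {
    sites <- sites[substr(sites$off_target, 22L, 23L) == "GG", , drop = FALSE]
  }
  sites <- label_by_concentration(sites, threshold_nM)
  repeats <- sample_inactive(sites, n_repeats = n_repeats, seed = seed)
  models <- train_models(repeats, ntree = ntree, seed = seed)
  ranking <- average_importance(models)
  sel <- backward_select(repeats, ranking, ntree = ntree, seed = seed)
  model <- select_final_model(repeats, sel$selected_features, ntree = ntree,
                              seed = seed, selection_curve = sel$curve)
  model$ranking <- ranking
  model
}
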