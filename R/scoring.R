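# Off-target activity scores: the MIT position-weight score, a CFD-style
# penalty-table score, the Random-Forest feature schema, and probability
# cut-off filtering.

#' MIT position penalties
#'
#' The 20 published per-position mismatch penalties (PAM-distal to
#' PAM-proximal) of the MIT specificity score.
#'
#' @return Numeric vector of length 20.
#' @export
mit_weights <- function() {
  c(0, 0, 0.014, 0, 0, 0.395, 0.317, 0, 0.389, 0.079,
    0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804, 0.685, 0.583)
}

#' MIT off-target score
#'
#' For mismatch positions `p1..pm` (1-based from the PAM-distal end) with
#' position penalties `W`:
#' \deqn{S = \prod_p (1 - W_p) \times \frac{1}{((19 - d)/19) \times 4 + 1}
#'   \times \frac{1}{m^2}}
#' where `m` is the mismatch count and `d` the mean pairwise distance
#' between mismatch positions. A perfect match scores 1; with a single
#' mismatch the distance term is 1 (the `d = 19` convention of the
#' reference implementations).
#'
#' Scoring always operates on guide-oriented 20-mers (the protospacer as
#' read 5'->3' with the PAM 3'), never on raw genome orientation.
#'
#' @param guide,offtarget 20-mer character vectors (recycled to a common
#'   length).
#' @param weights Position penalties, default [mit_weights()].
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
score_mit <- function(guide, offtarget, weights = mit_weights()) {
  n <- max(length(guide), length(offtarget))
  guide <- rep_len(guide, n)
  offtarget <- rep_len(offtarget, n)
  if (any(nchar(guide) != 20L) || any(nchar(offtarget) != 20L)) {
    abort("score_mit operates on 20-mer protospacers")
  }
  vapply(seq_len(n), function(i) {
    g <- s2c(guide[[i]])
    o <- s2c(offtarget[[i]])
    pos <- which(g != o)
    m <- length(pos)
    if (m == 0L) return(1)
    term1 <- prod(1 - weights[pos])
    d <- if (m == 1L) 19 else mean(utils::combn(pos, 2L, function(x) abs(diff(x))))
    term2 <- 1 / (((19 - d) / 19) * 4 + 1)
    term1 * term2 * (1 / m^2)
  }, numeric(1))
}

#' Load a CFD-style penalty table
#'
#' The table holds one penalty per (position, guide base, off-target base)
#' mismatch combination and one per PAM dinucleotide (the last two PAM
#' bases); matched base pairs implicitly score 1. The bundled default,
#' `cfd_penalty_table_synthetic.tsv`, is a synthetic stand-in generated
#' deterministically (PAM-proximal positions penalised more strongly,
#' transversions more than transitions, `GG` PAM = 1) -- it follows the
#' published table's layout and value ranges but does not reproduce the
#' published supplementary values, which must be supplied via `path` to
#' score with them.
#'
#' @param path Path to a penalty TSV with columns `type`
#'   (`"mismatch"`/`"pam"`), `position`, `guide_base`, `off_base`, `pam2`,
#'   `penalty`; `NULL` loads the bundled synthetic table.
#' @return An object of class `ot_cfd_table` (list with `mismatch` lookup
#'   environment and `pam` named vector).
#' @export
cfd_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cfd_penalty_table_synthetic.tsv",
                        package = "otvar", mustWork = TRUE)
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           type = "c", position = "i", guide_base = "c",
                           off_base = "c", pam2 = "c", penalty = "d"))
  if (any(tbl$penalty < 0 | tbl$penalty > 1)) {
    abort("CFD penalties must lie in [0, 1]")
  }
  mm <- tbl[tbl$type == "mismatch", , drop = FALSE]
  pam <- tbl[tbl$type == "pam", , drop = FALSE]
  mm_env <- new.env(parent = emptyenv(), size = nrow(mm))
  for (i in seq_len(nrow(mm))) {
    assign(paste0(mm$position[[i]], ":", mm$guide_base[[i]], ":",
                  mm$off_base[[i]]), mm$penalty[[i]], envir = mm_env)
  }
  structure(list(mismatch = mm_env,
                 pam = setNames(pam$penalty, pam$pam2),
                 source = path),
            class = "ot_cfd_table")
}

#' CFD-style off-target score
#'
#' Product over all mismatched positions of the (position, guide base,
#' off-target base) penalty, times the PAM penalty for the last two PAM
#' bases. Matched positions contribute 1. Missing table entries raise an
#' explicit lookup error, never a silent 0.
#'
#' @inheritParams score_mit
#' @param pam 3-mer PAM at the off-target site (recycled).
#' @param table An [cfd_table()] object.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
score_cfd <- function(guide, offtarget, pam, table = cfd_table()) {
  stopifnot(inherits(table, "ot_cfd_table"))
  n <- max(length(guide), length(offtarget), length(pam))
  guide <- rep_len(guide, n)
  offtarget <- rep_len(offtarget, n)
  pam <- rep_len(pam, n)
  if (any(nchar(guide) != 20L) || any(nchar(offtarget) != 20L)) {
    abort("score_cfd operates on 20-mer protospacers")
  }
  if (any(nchar(pam) != 3L)) abort("PAM must have length 3")
  vapply(seq_len(n), function(i) {
    g <- s2c(guide[[i]])
    o <- s2c(offtarget[[i]])
    s <- 1
    for (p in which(g != o)) {
      key <- paste0(p, ":", g[[p]], ":", o[[p]])
      if (!exists(key, envir = table$mismatch, inherits = FALSE)) {
        abort(sprintf("no CFD penalty for position %d, guide %s vs off-target %s",
                      p, g[[p]], o[[p]]))
      }
      s <- s * get(key, envir = table$mismatch)
    }
    pam2 <- substr(pam[[i]], 2L, 3L)
    if (!pam2 %in% names(table$pam)) {
      abort(sprintf("no CFD PAM penalty for N%s", pam2))
    }
    s * unname(table$pam[[pam2]])
  }, numeric(1))
}

# Feature schema --------------------------------------------------------------

SEED_START <- 9L  # positions 9..20 are the 12 bp PAM-proximal seed region

feature_names_v1 <- function() {
  pos2 <- sprintf("%02d", 1:20)
  c("mm_total", "mm_seed", "mm_nonseed", "mm_mean_pairdist",
    paste0("mm_pos_", pos2),
    paste0("ts_pos_", pos2),
    paste0("tv_pos_", pos2),
    as.vector(t(outer(paste0("mono_p", pos2, "_"), DNA_BASES, paste0))),
    as.vector(t(outer(paste0("di_p", sprintf("%02d", 1:19), "_"),
                      as.vector(t(outer(DNA_BASES, DNA_BASES, paste0))),
                      paste0))),
    "gc_content",
    "pam1_match",
    paste0("pam2_", DNA_BASES),
    paste0("pam3_", DNA_BASES))
}

#' Names and size of a feature schema
#'
#' @param schema_version Schema identifier; only `"1"` is defined.
#' @return Character vector of feature names (length 458 for schema 1).
#' @export
feature_schema <- function(schema_version = "1") {
  if (!identical(schema_version, "1")) {
    abort(sprintf("unknown feature schema version '%s'", schema_version))
  }
  feature_names_v1()
}

#' Extract model features for guide/off-target pairs
#'
#' Builds the numeric feature vector describing the relationship between an
#' on-target (guide) site and an off-target site. Schema version 1 has three
#' families: (a) mismatch properties -- total, seed (positions 9..20,
#' the 12 bp immediately PAM-proximal) and non-seed counts, mean pairwise
#' mismatch distance, and per-position mismatch / transition / transversion
#' indicators (a transition is a purine-purine or pyrimidine-pyrimidine
#' substitution, a transversion purine-pyrimidine); (b) sequence context of
#' the off-target protospacer -- position-specific one-hot mononucleotides
#' and dinucleotides plus GC content; (c) on-target relationship -- whether
#' the first PAM base of the off-target matches the on-target's, and a
#' one-hot encoding of the off-target PAM's 2nd and 3rd base.
#'
#' @param on_target,off_target Character vectors of 23-mers
#'   (protospacer + PAM), recycled to a common length.
#' @param schema_version Feature schema identifier.
#' @return A tibble with one row per pair and one column per feature; no
#'   missing values.
#' @export
extract_features <- function(on_target, off_target, schema_version = "1") {
  nms <- feature_schema(schema_version)
  n <- max(length(on_target), length(off_target))
  on_target <- rep_len(on_target, n)
  off_target <- rep_len(off_target, n)
  if (any(nchar(on_target) != 23L) || any(nchar(off_target) != 23L)) {
    abort("extract_features expects 23-mer protospacer+PAM sequences")
  }
  X <- matrix(0, nrow = n, ncol = length(nms), dimnames = list(NULL, nms))
  for (i in seq_len(n)) {
    g <- s2c(on_target[[i]])
    o <- s2c(off_target[[i]])
    gp <- g[1:20]; op <- o[1:20]
    mm <- which(gp != op)
    m <- length(mm)
    X[i, "mm_total"] <- m
    X[i, "mm_seed"] <- sum(mm >= SEED_START)
    X[i, "mm_nonseed"] <- sum(mm < SEED_START)
    X[i, "mm_mean_pairdist"] <- if (m >= 2L) {
      mean(utils::combn(mm, 2L, function(x) abs(diff(x))))
    } else 0
    for (p in mm) {
      pc <- sprintf("%02d", p)
      X[i, paste0("mm_pos_", pc)] <- 1
      if (is_purine(gp[[p]]) == is_purine(op[[p]])) {
        X[i, paste0("ts_pos_", pc)] <- 1
      } else {
        X[i, paste0("tv_pos_", pc)] <- 1
      }
    }
    for (p in 1:20) {
      X[i, paste0("mono_p", sprintf("%02d", p), "_", op[[p]])] <- 1
    }
    for (p in 1:19) {
      X[i, paste0("di_p", sprintf("%02d", p), "_", op[[p]], op[[p + 1L]])] <- 1
    }
    X[i, "gc_content"] <- mean(op %in% c("G", "C"))
    X[i, "pam1_match"] <- as.numeric(o[[21]] == g[[21]])
    X[i, paste0("pam2_", o[[22]])] <- 1
    X[i, paste0("pam3_", o[[23]])] <- 1
  }
  tibble::as_tibble(X)
}

#' Predict off-target activity probability
#'
#' Forest vote fraction for the active class. Features may be given in any
#' column order; they are matched by name and must cover the model's
#' selected features.
#'
#' @param model An `ot_model` (see [select_final_model()]).
#' @param features Feature tibble from [extract_features()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_activity <- function(model, features) {
  stopifnot(inherits(model, "ot_model"))
  missing <- setdiff(model$features, names(features))
  if (length(missing) > 0L) {
    abort(sprintf("feature schema mismatch: %d model feature(s) absent (e.g. %s)",
                  length(missing), missing[[1]]))
  }
  X <- as.data.frame(features[, model$features, drop = FALSE])
  unname(predict(model$forest, newdata = X, type = "prob")[, "active"])
}

#' Filter scored hits by an activity-probability cut-off
#'
#' Retains rows whose probability column is at least `threshold`. Retained
#' and removed counts are attached as attribute `cutoff_counts`.
#'
#' @param hits A tibble of scored hits.
#' @param threshold Probability cut-off in `[0, 1]`.
#' @param column Name of the probability column.
#' @return The retained rows.
#' @export
apply_cutoff <- function(hits, threshold = 0.5, column = "activity_prob") {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    abort("threshold must be a single probability in [0, 1]")
  }
  if (!column %in% names(hits)) {
    abort(sprintf("column '%s' not found in hits", column))
  }
  keep <- hits[[column]] >= threshold
  out <- hits[keep, , drop = FALSE]
  attr(out, "cutoff_counts") <- list(n_retained = sum(keep),
                                     n_removed = sum(!keep))
  out
}

#' TPR/FPR along a grid of probability thresholds
#'
#' @param prob Predicted probabilities.
#' @param label True labels (`"active"`/`"inactive"`).
#' @param thresholds Threshold grid.
#' @return Tibble with `threshold`, `tp`, `fp`, `tpr`, `fpr`.
#' @export
threshold_curve <- function(prob, label,
                            thresholds = seq(0, 1, by = 0.05)) {
  pos <- label == "active"
  dplyr::bind_rows(lapply(thresholds, function(t) {
    keep <- prob >= t
    tibble::tibble(threshold = t, tp = sum(keep & pos), fp = sum(keep & !pos),
                   tpr = if (sum(pos) > 0) sum(keep & pos) / sum(pos) else NA_real_,
                   fpr = if (sum(!pos) > 0) sum(keep & !pos) / sum(!pos) else NA_real_)
  }))
}
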