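# MTRX: a random-forest consensus of regional intolerance, combining the
# two sequence-window tolerance ratios (41- and 21-codon windows), the
# spatial tolerance ratio and relative solvent accessibility into a single
# probability-like score in [0, 1]; scores approaching 1 are more likely
# deleterious. The published combiner's weights and training data are not
# redistributable, so the package ships the trainable combiner plus a
# synthetic-label training recipe; reports always record training
# provenance.

MTRX_FEATURES <- c("mtr_v1", "mtr_v2", "mtr3d", "rsa")

#' Assemble an MTRX feature table for one gene
#'
#' @param gene A `GeneModel`.
#' @param mtr_v1,mtr_v2 `IntoleranceTrack`s from `compute_mtr()` with window
#'   sizes 41 and 21.
#' @param mtr3d An `IntoleranceTrack` from `compute_mtr3d()`.
#' @param rsa Data frame from `compute_rsa()`.
#' @param map The `SeqStructMap` used for `mtr3d` (links RSA residues to
#'   codons).
#' @return A data frame with `gene_id`, `codon_index` and the four feature
#'   columns; positions missing any feature keep `NA` there.
#' @export
mtrx_feature_table <- function(gene, mtr_v1, mtr_v2, mtr3d, rsa, map) {
  L <- gene$length
  rsa_by_codon <- rep(NA_real_, L)
  idx <- match(map$pairs$residue_id, rsa$residue_id)
  ok <- !is.na(idx)
  rsa_by_codon[map$pairs$codon_index[ok]] <- rsa$rsa[idx[ok]]
  data.frame(gene_id = gene$gene_id, codon_index = seq_len(L),
             mtr_v1 = mtr_v1$score, mtr_v2 = mtr_v2$score,
             mtr3d = mtr3d$score, rsa = rsa_by_codon,
             stringsAsFactors = FALSE)
}

#' Train the MTRX random-forest combiner
#'
#' @param rows Data frame with the feature columns `mtr_v1`, `mtr_v2`,
#'   `mtr3d`, `rsa` and a `label` column with two classes (`"deleterious"`,
#'   `"benign"`). Rows with any missing feature are excluded from training.
#' @param seed Integer seed; fixing it makes training (and therefore every
#'   emitted score) reproducible bit for bit.
#' @param ntree Number of trees (default 500).
#' @return An `MTRXModel`: list with the fitted forest, feature list, seed,
#'   training size and out-of-bag error summary.
#' @export
train_mtrx <- function(rows, seed = 20230307L, ntree = 500L) {
  miss <- setdiff(c(MTRX_FEATURES, "label"), names(rows))
  if (length(miss) > 0) {
    stop("training rows lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(rows[, MTRX_FEATURES]) & !is.na(rows$label)
  rows <- rows[complete, , drop = FALSE]
  classes <- unique(rows$label)
  if (length(classes) < 2) {
    stop("training data must contain two classes, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  y <- factor(rows$label, levels = c("benign", "deleterious"))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = rows[, MTRX_FEATURES], y = y, ntree = ntree, importance = TRUE
  )
  structure(list(forest = forest, features = MTRX_FEATURES, seed = seed,
                 n_train = nrow(rows),
                 oob_error = unname(forest$err.rate[ntree, "OOB"])),
            class = "MTRXModel")
}

#' @export
print.MTRXModel <- function(x, ...) {
  cat(sprintf("<MTRXModel: %d trees, %d training rows, OOB error %.3f, seed %d>\n",
              x$forest$ntree, x$n_train, x$oob_error, x$seed))
  invisible(x)
}

#' Score positions with a trained MTRX model
#'
#' @param model An `MTRXModel`.
#' @param rows Feature data frame (as from `mtrx_feature_table()`).
#' @return Numeric vector of P(deleterious) in `[0, 1]`, `NA` wherever any
#'   required feature is missing.
#' @export
score_mtrx <- function(model, rows) {
  miss <- setdiff(model$features, names(rows))
  if (length(miss) > 0) {
    stop("feature column(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_real_, nrow(rows))
  complete <- stats::complete.cases(rows[, model$features])
  if (any(complete)) {
    p <- stats::predict(model$forest, rows[complete, model$features],
                        type = "prob")
    out[complete] <- p[, "deleterious"]
  }
  out
}

#' Synthetic-label MTRX training recipe
#'
#' Labels positions deleterious when `mtr_v2` falls strictly below `cutoff`
#' -- a noise-free, separable task used as the shipped self-test recipe in
#' place of the unrecoverable published training set.
#'
#' @param rows Feature data frame.
#' @param cutoff Labelling cutoff on `mtr_v2` (default 0.5).
#' @return `rows` with a `label` column added.
#' @export
mtrx_synthetic_labels <- function(rows, cutoff = 0.5) {
  rows$label <- ifelse(is.na(rows$mtr_v2), NA_character_,
                       ifelse(rows$mtr_v2 < cutoff, "deleterious", "benign"))
  rows
}

#' MTRX holdout self-test
#'
#' Stratified 80/20 split of labelled rows, trains on the 80% and reports
#' held-out accuracy and AUC.
#'
#' @param rows Labelled feature data frame (two classes, complete features).
#' @param seed Integer seed controlling the split and the forest.
#' @param ntree Number of trees.
#' @return A list with `accuracy`, `auc`, `n_train`, `n_test` and the fitted
#'   `model`.
#' @export
mtrx_self_test <- function(rows, seed = 20230307L, ntree = 500L) {
  complete <- stats::complete.cases(rows[, MTRX_FEATURES]) & !is.na(rows$label)
  rows <- rows[complete, , drop = FALSE]
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_len(nrow(rows)), rows$label),
                            function(ix) sample(ix, max(1, round(0.2 * length(ix))))))
  train <- rows[-test_idx, , drop = FALSE]
  test <- rows[test_idx, , drop = FALSE]
  model <- train_mtrx(train, seed = seed, ntree = ntree)
  p <- score_mtrx(model, test)
  pred <- ifelse(p >= 0.5, "deleterious", "benign")
  truth <- test$label == "deleterious"
  # rank-based AUC (Mann-Whitney formulation)
  r <- rank(p)
  n1 <- sum(truth); n0 <- sum(!truth)
  auc <- if (n1 > 0 && n0 > 0) (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
         else NA_real_
  list(accuracy = mean(pred == test$label), auc = auc,
       n_train = nrow(train), n_test = nrow(test), model = model)
}
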