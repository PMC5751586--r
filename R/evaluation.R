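# Evaluation protocol: negative-set construction, stratified k-fold
# cross-validation, confusion-matrix metrics, ROC curves, AUC, and the
# parameter-sweep harness.

#' Confusion counts
#'
#' @param truth logical vector (TRUE = positive) or factor/character with
#'   positives identified by `positive`.
#' @param predicted same form as `truth`.
#' @param positive label treated as the positive class for non-logical input.
#' @return List of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "piRNA") {
  if (!is.logical(truth)) truth <- truth == positive
  if (!is.logical(predicted)) predicted <- predicted == positive
  stopifnot(length(truth) == length(predicted))
  structure(list(TP = sum(truth & predicted),
                 TN = sum(!truth & !predicted),
                 FP = sum(!truth & predicted),
                 FN = sum(truth & !predicted)),
            class = "confusion_counts")
}

#' Accuracy, true-positive rate and false-positive rate
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `TPR = TP/(TP+FN)`, `FPR = FP/(TN+FP)`.
#'
#' @param counts a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return Named numeric vector `c(ACC, TPR, FPR)`.
#' @export
metrics <- function(counts) {
  with(counts, {
    if (TP + TN + FP + FN == 0) stop("ACC undefined: no samples",
                                     call. = FALSE)
    if (TP + FN == 0) stop("TPR undefined: no positives", call. = FALSE)
    if (TN + FP == 0) stop("FPR undefined: no negatives", call. = FALSE)
    c(ACC = (TP + TN) / (TP + TN + FP + FN),
      TPR = TP / (TP + FN),
      FPR = FP / (TN + FP))
  })
}

#' Length-matched shuffled negative controls
#'
#' For each positive sequence, draws a window of the same length uniformly
#' from a uniformly chosen background record that is long enough, and
#' mononucleotide-shuffles it. The negatives thus match the positives'
#' length profile and the background's local base composition but carry none
#' of its k-gram structure.
#'
#' @param pos positive [seq_set].
#' @param background background [seq_set] (e.g. ncRNA sequences).
#' @param rng_seed integer seed.
#' @return A [seq_set] with one negative per positive, ids `neg_<pos id>`.
#' @export
make_negatives <- function(pos, background, rng_seed) {
  bg_len <- nchar(background$seq)
  withr::with_seed(rng_seed, {
    seqs <- vapply(seq_along(pos$id), function(i) {
      len <- nchar(pos$seq[i])
      eligible <- which(bg_len >= len)
      if (length(eligible) == 0L) {
        stop("no background sequence of length >= ", len, call. = FALSE)
      }
      src <- background$seq[eligible[sample.int(length(eligible), 1L)]]
      start <- sample.int(nchar(src) - len + 1L, 1L)
      chars <- strsplit(substr(src, start, start + len - 1L), "",
                        fixed = TRUE)[[1L]]
      paste(sample(chars), collapse = "")
    }, character(1))
  })
  seq_set(paste0("neg_", pos$id), seqs)
}

#' ROC curve and area under it
#'
#' `roc_curve()` sweeps the decision threshold over the score values from
#' strict to lenient and reports (FPR, TPR) at each step, starting at (0,0)
#' and ending at (1,1); `auc()` integrates that curve by the trapezoidal
#' rule. For separable or tied score sets this equals the Mann-Whitney
#' U-statistic estimate of P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (TRUE = positive) or factor/character with
#'   `positive` as the positive label.
#' @param positive positive class label for non-logical `labels`.
#' @return `roc_curve()`: data frame with columns `threshold`, `FPR`, `TPR`;
#'   `auc()`: a single number in \[0, 1\].
#' @export
roc_curve <- function(scores, labels, positive = "piRNA") {
  if (!is.logical(labels)) labels <- labels == positive
  stopifnot(length(scores) == length(labels), sum(labels) > 0,
            sum(!labels) > 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # merge tied scores into single steps
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tpr <- cumsum(y)[keep] / sum(y)
  fpr <- cumsum(!y)[keep] / sum(!y)
  data.frame(threshold = c(Inf, s[keep]),
             FPR = c(0, fpr), TPR = c(0, tpr))
}

#' @rdname roc_curve
#' @export
auc <- function(scores, labels, positive = "piRNA") {
  r <- roc_curve(scores, labels, positive)
  sum(diff(r$FPR) * (r$TPR[-1L] + r$TPR[-nrow(r)]) / 2)
}

#' Stratified k-fold cross-validation of a detector
#'
#' Positives and negatives are each randomly partitioned into `k` folds of
#' near-equal size (stratified, so every fold keeps the class balance); each
#' fold in turn is held out for testing while the trainer fits on the rest.
#' Scores are pooled across folds for the overall ROC/AUC; per-fold
#' confusion counts, metrics and AUCs are also reported.
#'
#' @param pos,neg positive / negative [seq_set]s (each of size >= `k`).
#' @param k number of folds (default 5).
#' @param trainer function `(train_pos, train_neg) -> function(seqs) ->
#'   numeric scores` (higher = more piRNA-like). See [ngm_trainer] and
#'   [kmer_trainer].
#' @param rng_seed integer seed for the fold assignment.
#' @param threshold decision threshold on the scores for the confusion
#'   counts (default 0.5, matching confidence-probability scorers).
#' @return An `eval_report`: list with `folds` (per-fold data frame of
#'   counts, ACC/TPR/FPR and AUC), `ACC`, `TPR`, `FPR` (fold averages),
#'   `roc` (pooled curve), `auc` (pooled, in \[0,1\]), `auc_pct`
#'   (`100 * auc`), `scores` (pooled data frame of id, score, truth, fold),
#'   `k`, `rng_seed`, `threshold`.
#' @export
crossvalidate <- function(pos, neg, k = 5L, trainer, rng_seed = 1L,
                          threshold = 0.5) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (length(pos) < k || length(neg) < k) {
    stop("each class needs at least k sequences", call. = FALSE)
  }
  fold_pos <- withr::with_seed(rng_seed, sample(rep_len(1:k, length(pos))))
  fold_neg <- withr::with_seed(derive_seed(rng_seed, 1L),
                               sample(rep_len(1:k, length(neg))))
  all_scores <- list()
  fold_rows <- list()
  for (f in 1:k) {
    scorer <- trainer(pos[fold_pos != f], neg[fold_neg != f])
    sp <- scorer(pos[fold_pos == f])
    sn <- scorer(neg[fold_neg == f])
    truth <- c(rep(TRUE, length(sp)), rep(FALSE, length(sn)))
    sc <- c(sp, sn)
    cc <- confusion_counts(truth, sc >= threshold)
    m <- metrics(cc)
    fold_rows[[f]] <- data.frame(fold = f, TP = cc$TP, TN = cc$TN,
                                 FP = cc$FP, FN = cc$FN,
                                 ACC = m["ACC"], TPR = m["TPR"],
                                 FPR = m["FPR"],
                                 AUC = auc(sc, truth), row.names = NULL)
    all_scores[[f]] <- data.frame(
      id = c(pos$id[fold_pos == f], neg$id[fold_neg == f]),
      score = sc, truth = truth, fold = f, stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, fold_rows)
  pooled <- do.call(rbind, all_scores)
  structure(list(folds = folds,
                 ACC = mean(folds$ACC), TPR = mean(folds$TPR),
                 FPR = mean(folds$FPR),
                 roc = roc_curve(pooled$score, pooled$truth),
                 auc = auc(pooled$score, pooled$truth),
                 auc_pct = 100 * auc(pooled$score, pooled$truth),
                 scores = pooled, k = k, rng_seed = rng_seed,
                 threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV: ACC=%.4f TPR=%.4f FPR=%.4f AUC=%.2f\n",
              x$k, x$ACC, x$TPR, x$FPR, x$auc_pct))
  invisible(x)
}

#' Trainer factories for cross-validation
#'
#' `ngm_trainer()` wraps [train_detector]/[predict.pirna_detector]:
#' the returned scorer reports the detector's confidence probability.
#' `kmer_trainer()` wraps [kmer_classify]; for `method = "logodds"` the raw
#' log-odds score is squashed through a logistic so it lives on the same
#' \[0,1\] scale (the cutoff `t` maps to 0.5), leaving the ROC unchanged.
#'
#' @param params,svm_config passed to [train_detector].
#' @param cutoff,method,ksvm_config passed to [kmer_classify]
#'   (`ksvm_config` = its `svm_config`).
#' @return A trainer function for [crossvalidate].
#' @export
ngm_trainer <- function(params = clustering_params(), svm_config = list()) {
  function(train_pos, train_neg) {
    det <- train_detector(train_pos, train_neg, params, svm_config)
    function(seqs) {
      p <- stats::predict(det, seqs)
      stats::setNames(p$confidence, p$id)
    }
  }
}

#' @rdname ngm_trainer
#' @export
kmer_trainer <- function(cutoff = 1.2, method = "logodds",
                         ksvm_config = list()) {
  function(train_pos, train_neg) {
    function(seqs) {
      r <- kmer_classify(train_pos, train_neg, seqs, cutoff = cutoff,
                         method = method, svm_config = ksvm_config)
      s <- if (method == "logodds") stats::plogis(r$score - cutoff) else r$score
      stats::setNames(s, r$id)
    }
  }
}

#' Parameter sweep over dataset size and clustering thresholds
#'
#' For every combination of dataset size, `N_th` and `Z_th`, subsamples the
#' positives (and matching negatives), runs k-fold cross-validation with the
#' NGM detector, and records the mean accuracy, mean AUC and the mean number
#' of families built per fold — the harness behind accuracy-vs-size trend
#' plots.
#'
#' Cells where no fold finds any family get `NA` accuracy and a family count
#' of 0.
#'
#' @param pos,neg labelled [seq_set]s to subsample from.
#' @param sizes integer vector of per-class dataset sizes.
#' @param N_th_values,Z_th_values threshold grids.
#' @param params base [clustering_params] (its `N_th`/`Z_th` are overridden
#'   per cell).
#' @param svm_config passed to the trainer.
#' @param k folds (default 5).
#' @param rng_seed integer seed.
#' @return Data frame with one row per cell: `size`, `N_th`, `Z_th`, `ACC`,
#'   `AUC`, `families` (mean per fold).
#' @export
parameter_sweep <- function(pos, neg, sizes, N_th_values, Z_th_values,
                            params = clustering_params(),
                            svm_config = list(), k = 5L, rng_seed = 1L) {
  grid <- expand.grid(size = as.integer(sizes),
                      N_th = as.integer(N_th_values),
                      Z_th = Z_th_values, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sz <- min(g$size, length(pos), length(neg))
    idx_p <- withr::with_seed(derive_seed(rng_seed, i),
                              sample.int(length(pos), sz))
    idx_n <- withr::with_seed(derive_seed(rng_seed, i + nrow(grid)),
                              sample.int(length(neg), sz))
    p <- params; p$N_th <- g$N_th; p$Z_th <- g$Z_th
    fam_counts <- integer(0)
    counting_trainer <- function(train_pos, train_neg) {
      res <- tryCatch(train_detector(train_pos, train_neg, p, svm_config),
                      error = function(e) NULL)
      fam_counts <<- c(fam_counts,
                       if (is.null(res)) 0L else length(res$families))
      if (is.null(res)) {
        function(seqs) stats::setNames(rep(0.5, length(seqs)), seqs$id)
      } else {
        function(seqs) {
          pr <- stats::predict(res, seqs)
          stats::setNames(pr$confidence, pr$id)
        }
      }
    }
    rep_ <- crossvalidate(pos[idx_p], neg[idx_n], k = k,
                          trainer = counting_trainer,
                          rng_seed = derive_seed(rng_seed, 2L * i))
    data.frame(size = sz, N_th = g$N_th, Z_th = g$Z_th,
               ACC = if (all(fam_counts == 0L)) NA_real_ else rep_$ACC,
               AUC = if (all(fam_counts == 0L)) NA_real_ else rep_$auc_pct,
               families = mean(fam_counts))
  })
  do.call(rbind, rows)
}

#' Count the families a clustering finds at given thresholds
#'
#' Lightweight companion to [parameter_sweep] for trend checks that only
#' need the number of families (no cross-validation).
#'
#' @param dataset a [seq_set].
#' @param params a [clustering_params].
#' @return Integer number of families.
#' @export
count_families <- function(dataset, params = clustering_params()) {
  if (params$N_th > length(dataset)) return(0L)
  length(cluster_all(dataset, params)$families)
}
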