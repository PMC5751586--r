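# K-mer baseline: the 1,364-feature counting scheme (all k-mers, k = 1..5)
# with a cutoff-parameter decision rule, plus an SVM back-end over the same
# features for an apples-to-apples comparison with the NGM detector.

KMER_KS <- 1:5
KMER_FEATURE_COUNT <- sum(4^KMER_KS)  # 4 + 16 + 64 + 256 + 1024 = 1364

#' K-mer count features
#'
#' Overlapping occurrence counts of every k-mer for k = 1..5, ordered by k
#' ascending then lexicographically (A < C < G < T): 1,364 features in total.
#' For each k the counts sum to `max(len - k + 1, 0)`.
#'
#' @param x a [seq_set] or a character vector of A/C/G/T sequences.
#' @return Integer matrix, one row per sequence, 1,364 named columns.
#' @export
kmer_features <- function(x) {
  seqs <- if (inherits(x, "seq_set")) x$seq else as.character(x)
  ids <- if (inherits(x, "seq_set")) x$id else names(x)
  dna <- Biostrings::DNAStringSet(seqs)
  m <- do.call(cbind, lapply(KMER_KS, function(k)
    Biostrings::oligonucleotideFrequency(dna, width = k)))
  rownames(m) <- ids
  m
}

# Laplace-smoothed class-conditional k-mer frequencies from pooled counts.
.kmer_class_freq <- function(counts) {
  f <- numeric(KMER_FEATURE_COUNT)
  col0 <- 0L
  total <- colSums(counts)
  for (k in KMER_KS) {
    idx <- col0 + seq_len(4^k)
    f[idx] <- (total[idx] + 1) / (sum(total[idx]) + 4^k)
    col0 <- col0 + 4L^k
  }
  f
}

#' K-mer baseline classifier
#'
#' Reimplements the comparison scheme that scores sequences from their k-mer
#' frequency profile and calls piRNA when the score reaches a cutoff `t`
#' (default 1.2). The published description of the original scheme does not
#' fix the scoring formula, so this implementation uses a length-normalised
#' log-odds score,
#' `score(b) = sum_w count_w(b) * log(f_pos(w) / f_neg(w)) / nchar(b)`,
#' with Laplace-smoothed per-class frequencies `f_pos`, `f_neg` estimated per
#' k from the pooled training counts — a stand-in honouring the stated
#' interface (frequency-based score plus cutoff). Varying `t` traces the ROC.
#' The `"svm"` method instead feeds the 1,364 per-k-normalised frequencies to
#' an RBF-kernel c-classification SVM with a logistic confidence map (scores
#' are then confidences in \[0,1\] and `t` is applied to them, so use the
#' default 0.5 scale there).
#'
#' @param train_pos,train_neg training [seq_set]s (non-empty).
#' @param test test [seq_set].
#' @param cutoff decision cutoff `t` on the score (default 1.2 for
#'   `"logodds"`).
#' @param method `"logodds"` (default) or `"svm"`.
#' @param svm_config for `method = "svm"`: list with `cost` (default 1) and
#'   `gamma` (default `1/1364`).
#' @return Data frame with columns `id`, `score`, `label`, in test order.
#' @export
kmer_classify <- function(train_pos, train_neg, test, cutoff = 1.2,
                          method = c("logodds", "svm"),
                          svm_config = list()) {
  method <- match.arg(method)
  if (length(train_pos) == 0L || length(train_neg) == 0L) {
    stop("both training classes must be non-empty", call. = FALSE)
  }
  if (method == "logodds") {
    w <- log(.kmer_class_freq(kmer_features(train_pos)) /
               .kmer_class_freq(kmer_features(train_neg)))
    counts <- kmer_features(test)
    score <- as.numeric(counts %*% w) / nchar(test$seq)
  } else {
    cfg <- utils::modifyList(list(cost = 1, gamma = 1 / KMER_FEATURE_COUNT),
                             svm_config)
    x <- .kmer_freq_matrix(rbind(kmer_features(train_pos),
                                 kmer_features(train_neg)),
                           c(nchar(train_pos$seq), nchar(train_neg$seq)))
    y <- factor(c(rep("piRNA", length(train_pos)),
                  rep("non-piRNA", length(train_neg))),
                levels = c("non-piRNA", "piRNA"))
    fit <- e1071::svm(x = x, y = y, type = "C-classification",
                      kernel = "radial", cost = cfg$cost, gamma = cfg$gamma,
                      scale = FALSE)
    platt <- .fit_platt(.decision_pirna(fit, x), as.integer(y == "piRNA"))
    xt <- .kmer_freq_matrix(kmer_features(test), nchar(test$seq))
    score <- .platt_prob(platt, .decision_pirna(fit, xt))
  }
  data.frame(id = test$id, score = score,
             label = ifelse(score >= cutoff, "piRNA", "non-piRNA"),
             stringsAsFactors = FALSE)
}

# counts -> per-k relative frequencies (each k block divided by its window
# count), so features are on comparable scales for the SVM.
.kmer_freq_matrix <- function(counts, lens) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  col0 <- 0L
  for (k in KMER_KS) {
    idx <- col0 + seq_len(4^k)
    denom <- pmax(lens - k + 1L, 1L)
    out[, idx] <- counts[, idx, drop = FALSE] / denom
    col0 <- col0 + 4L^k
  }
  out
}
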