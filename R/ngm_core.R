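# n-gram Markov models (NGMs): fitting with pseudo-counts, windowed
# log-likelihood scoring, and the max-over-windows similarity scan.
#
# An n-gram model is an (n-1)th-order Markov chain over {A,C,G,T}: the
# probability of each base depends on the preceding n-1 bases. A length-L
# window starting at 0-based offset k of sequence b is scored by
#
#   R(b, k) = log P(g_k) + sum_{i=k+n}^{k+L} log P(b_i | b_{i-n+1..i-1})
#
# where g_k is the (n-1)-gram opening the window (positions written 1-based
# here, matching the usual Markov-chain factorisation). Logs are natural;
# downstream Z-score standardisation makes the base immaterial, but it is
# fixed so serialized scores are comparable.

new_ngram_model <- function(n, pseudo_count, state_prob, trans_prob,
                            trained_on) {
  structure(list(
    n = as.integer(n),
    pseudo_count = pseudo_count,
    state_prob = state_prob,    # named vector, 4^(n-1) entries
    trans_prob = trans_prob,    # 4^(n-1) x 4 matrix, rows = contexts
    log_state = log(state_prob),
    # flat log transition table indexed by n-gram index (context*4 + base)
    log_trans_flat = as.vector(t(log(trans_prob))),
    trained_on = as.integer(trained_on)
  ), class = "ngram_model")
}

#' Fit an n-gram Markov model
#'
#' Estimates the state distribution over (n-1)-grams and the base transition
#' probabilities from all overlapping windows of the training sequences, with
#' additive (pseudo-count) smoothing so that every probability is strictly
#' positive — the smoothing stands in for unobserved point mutations.
#'
#' State probabilities are estimated from every (n-1)-gram window of every
#' training sequence (not only window-initial positions), which is essential
#' for 26-36 nt sequences where counts are scarce.
#'
#' @param training a [seq_set] of training sequences, each of length >= `n`.
#' @param n gram size (model order is `n - 1`); default 4, the tetragram.
#' @param pseudo_count additive smoothing constant alpha > 0.
#' @return An object of class `ngram_model`.
#' @export
fit_ngm <- function(training, n = 4L, pseudo_count = 1) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (pseudo_count <= 0) stop("pseudo_count must be > 0", call. = FALSE)
  if (length(training) == 0L) stop("empty training set", call. = FALSE)
  short <- nchar(training$seq) < n
  if (any(short)) {
    stop("training sequence shorter than n: ",
         training$id[which(short)[1L]], call. = FALSE)
  }
  n_ctx <- 4L^(n - 1L)
  state_counts <- numeric(n_ctx)
  ngram_counts <- numeric(4L * n_ctx)
  for (s in training$seq) {
    codes <- encode_seq(s)
    state_counts <- state_counts + tabulate(gram_indices(codes, n - 1L), n_ctx)
    ngram_counts <- ngram_counts +
      tabulate(gram_indices(codes, n), 4L * n_ctx)
  }
  state_prob <- (state_counts + pseudo_count) /
    (sum(state_counts) + pseudo_count * n_ctx)
  names(state_prob) <- all_grams(n - 1L)
  cnt <- matrix(ngram_counts, nrow = n_ctx, ncol = 4L, byrow = TRUE,
                dimnames = list(all_grams(n - 1L), .BASES))
  trans_prob <- (cnt + pseudo_count) / (rowSums(cnt) + 4 * pseudo_count)
  new_ngram_model(n, pseudo_count, state_prob, trans_prob, length(training))
}

#' Uniform (pure pseudo-count) n-gram model
#'
#' The model obtained from zero observations: every transition probability is
#' 1/4 and every state probability 1/4^(n-1). Mainly useful as an analytic
#' reference in tests.
#'
#' @inheritParams fit_ngm
#' @return An `ngram_model`.
#' @export
uniform_model <- function(n = 4L, pseudo_count = 1) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  n_ctx <- 4L^(n - 1L)
  state_prob <- stats::setNames(rep(1 / n_ctx, n_ctx), all_grams(n - 1L))
  trans_prob <- matrix(0.25, nrow = n_ctx, ncol = 4L,
                       dimnames = list(all_grams(n - 1L), .BASES))
  new_ngram_model(n, pseudo_count, state_prob, trans_prob, 0L)
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("<ngram_model> n=%d (order-%d Markov chain), alpha=%g, %d training sequence(s)\n",
              x$n, x$n - 1L, x$pseudo_count, x$trained_on))
  invisible(x)
}

# log transition terms for positions n..len and log state terms for every
# (n-1)-gram start; shared by loglik_window and scan_max_similarity.
.window_terms <- function(model, codes) {
  list(
    g = model$log_state[gram_indices(codes, model$n - 1L)],
    t = model$log_trans_flat[gram_indices(codes, model$n)]
  )
}

#' Windowed log-likelihood under an n-gram model
#'
#' Scores the length-`L` window of `seq` starting at 0-based offset `k`: the
#' log state probability of the opening (n-1)-gram plus the summed log
#' transition probabilities of the remaining `L - n + 1` bases (natural log).
#'
#' @param model an `ngram_model`.
#' @param seq a single character string over \{A,C,G,T\}.
#' @param k 0-based window offset, `0 <= k <= nchar(seq) - L`.
#' @param L window length, `L >= model$n`.
#' @return The log-likelihood (a single numeric value).
#' @export
loglik_window <- function(model, seq, k, L) {
  codes <- encode_seq(seq)
  len <- length(codes)
  L <- as.integer(L); k <- as.integer(k)
  if (L < model$n) stop("window length L must be >= n", call. = FALSE)
  if (k < 0L || k + L > len) stop("window [", k, ", ", k + L,
                                  ") out of bounds for length ", len,
                                  call. = FALSE)
  tm <- .window_terms(model, codes)
  # transitions cover window positions n..L, i.e. t indices (k+1)..(k+L-n+1)
  unname(tm$g[k + 1L] + sum(tm$t[(k + 1L):(k + L - model$n + 1L)]))
}

#' Maximum sliding-window similarity S(b)
#'
#' Scans every length-`L` window of `seq` and returns the maximal windowed
#' log-likelihood together with its offset — the raw homology similarity of
#' the sequence to the model. Successive windows are scored by an O(1)
#' incremental update (drop the leading terms, add the trailing transition),
#' realised here through a single cumulative sum over per-position transition
#' terms; the result is identical to independently rescoring every window.
#' Ties are broken toward the smallest offset.
#'
#' @inheritParams loglik_window
#' @param L window length, `model$n <= L <= nchar(seq)`.
#' @return A list of class `similarity_score` with elements `value`
#'   (log-likelihood), `offset` (0-based best offset) and `window_length`.
#' @export
scan_max_similarity <- function(model, seq, L) {
  codes <- encode_seq(seq)
  len <- length(codes)
  L <- as.integer(L)
  if (L < model$n) stop("window length L must be >= n", call. = FALSE)
  if (len < L) stop("sequence shorter than window length ", L, call. = FALSE)
  tm <- .window_terms(model, codes)
  nk <- len - L + 1L                 # number of candidate offsets
  cs <- c(0, cumsum(tm$t))
  span <- L - model$n + 1L           # transitions per window
  r <- tm$g[seq_len(nk)] + cs[seq_len(nk) + span] - cs[seq_len(nk)]
  best <- unname(which.max(r))       # first maximum = smallest offset
  structure(list(value = unname(r[best]), offset = best - 1L,
                 window_length = L), class = "similarity_score")
}

# Batch similarity over a seq_set; the window is capped at each sequence's
# own length. Returns a numeric vector named by sequence id.
scan_set_similarity <- function(model, x, L) {
  vapply(seq_along(x$id), function(i) {
    Lw <- min(L, nchar(x$seq[i]))
    scan_max_similarity(model, x$seq[i], Lw)$value
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, x$id)
}

#' Serialize and restore an n-gram model
#'
#' Models are stored as a self-describing JSON document holding `n`, the
#' pseudo-count, and both probability tables at full double precision, so a
#' write/read round trip is exact.
#'
#' @param model an `ngram_model`.
#' @param path file path.
#' @return `write_ngm()`: `path`, invisibly; `read_ngm()`: the restored
#'   `ngram_model`.
#' @export
write_ngm <- function(model, path) {
  doc <- list(
    type = "ngram_model",
    n = model$n,
    pseudo_count = model$pseudo_count,
    trained_on = model$trained_on,
    state_prob = as.list(model$state_prob),
    trans_prob = stats::setNames(
      lapply(seq_len(nrow(model$trans_prob)),
             function(i) unname(model$trans_prob[i, ])),
      rownames(model$trans_prob))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ngm
#' @export
read_ngm <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "ngram_model")) {
    stop("not an ngram_model document: ", path, call. = FALSE)
  }
  n <- as.integer(doc$n)
  state_prob <- unlist(doc$state_prob)
  trans_prob <- do.call(rbind, lapply(doc$trans_prob, unlist))
  colnames(trans_prob) <- .BASES
  new_ngram_model(n, doc$pseudo_count, state_prob, trans_prob,
                  doc$trained_on)
}
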