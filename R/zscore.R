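# Z-score calibration of raw similarities against shuffled null ensembles.
#
# Raw similarities S(b) depend strongly on sequence length and on the score
# scale of the particular model, so they are standardised:
#
#   Z(b) = (S(b) - mu) / sigma
#
# where mu and sigma are the mean and standard deviation of S over a null
# ensemble of Monte-Carlo shuffled sequences. Two calibration flavours are
# used: a single fixed-length null during family clustering (one scalar
# mu/sigma at the dataset's minimum length), and a multi-length ensemble with
# a regression of mu(length) and sigma(length) at detection time, so that
# candidate sequences of any length in the piRNA range get a comparable
# Z-score.

#' Build a shuffled null ensemble
#'
#' Draws `size` sequences of exactly `length` bases: each is a uniformly
#' chosen window of that length from a uniformly chosen source sequence (only
#' sequences long enough are eligible), then mononucleotide-shuffled. The
#' shuffle preserves each window's base composition while destroying its
#' n-gram structure, which is what the similarity scan keys on.
#'
#' @param source a [seq_set] to draw windows from.
#' @param length target sequence length (every output has exactly this
#'   length).
#' @param size number of sequences to generate.
#' @param rng_seed integer seed; the ensemble is fully reproducible from it.
#' @return A [seq_set] of `size` shuffled sequences.
#' @export
build_ensemble <- function(source, length, size, rng_seed) {
  length <- as.integer(length); size <- as.integer(size)
  if (size < 2L) stop("ensemble size must be >= 2", call. = FALSE)
  if (length(source) == 0L) stop("empty source set", call. = FALSE)
  eligible <- which(nchar(source$seq) >= length)
  if (length(eligible) == 0L) {
    stop("no source sequence of length >= ", length, call. = FALSE)
  }
  withr::with_seed(rng_seed, {
    picks <- sample(eligible, size, replace = TRUE)
    seqs <- vapply(picks, function(i) {
      s <- source$seq[i]
      start <- sample.int(nchar(s) - length + 1L, 1L)
      chars <- strsplit(substr(s, start, start + length - 1L), "", fixed = TRUE)[[1L]]
      paste(sample(chars), collapse = "")
    }, character(1))
  })
  seq_set(sprintf("shuf%06d", seq_len(size)), seqs)
}

# Scalar null statistics for the clustering stage: mu and sigma of S over an
# ensemble of mononucleotide-shuffled source sequences. Each null sequence is
# a whole source sequence shuffled in place (its length preserved) and scored
# exactly like the real sequences (max over length-L windows), so the null
# matches the pool's length profile and scoring geometry -- a fixed-length
# null would understate the scores of longer sequences, which see more
# candidate windows.
null_stats <- function(model, source, L, ensemble_size, rng_seed) {
  if (length(source) == 0L) stop("empty source set", call. = FALSE)
  withr::with_seed(rng_seed, {
    picks <- sample.int(length(source), ensemble_size, replace = TRUE)
    seqs <- vapply(picks, function(i) {
      paste(sample(strsplit(source$seq[i], "", fixed = TRUE)[[1L]]),
            collapse = "")
    }, character(1))
  })
  ens <- seq_set(sprintf("shuf%06d", seq_len(ensemble_size)), seqs)
  s <- scan_set_similarity(model, ens, L)
  sigma <- stats::sd(s)
  if (!is.finite(sigma) || sigma < 1e-12) {
    stop("degenerate null ensemble: sigma ~ 0 at length ", L, call. = FALSE)
  }
  structure(list(mu = mean(s), sigma = sigma, L = L,
                 ensemble_size = ensemble_size, rng_seed = rng_seed),
            class = "z_null")
}

# Fit a 1-d regression y ~ x for the calibration curves. The default is
# epsilon-SVR with an RBF kernel (inputs standardised internally, so the
# kernel width is 1 / variance of the standardised feature); "lm" fits a
# quadratic polynomial instead. With four anchor points any smooth
# interpolator satisfying the anchored-regression tolerance is acceptable,
# so the family is pluggable.
.fit_curve <- function(x, y, regression, cost, epsilon) {
  if (regression == "svr") {
    if (stats::sd(y) < 1e-12) {
      # constant curve: SVR with scaled y is undefined; short-circuit
      f <- local({ c0 <- y[1L]; function(z) rep(c0, length(z)) })
      return(f)
    }
    fit <- e1071::svm(x = matrix(x, ncol = 1), y = y,
                      type = "eps-regression", kernel = "radial",
                      cost = cost, epsilon = epsilon, gamma = 1,
                      scale = TRUE)
    function(z) as.numeric(stats::predict(fit, matrix(z, ncol = 1)))
  } else {
    deg <- min(2L, length(unique(x)) - 1L)
    df <- data.frame(x = x, x2 = x^2, y = y)
    fit <- if (deg >= 2L) stats::lm(y ~ x + x2, data = df)
           else stats::lm(y ~ x, data = df)
    function(z) as.numeric(stats::predict(fit, data.frame(x = z, x2 = z^2)))
  }
}

#' Calibrate length-dependent Z-score parameters for a model
#'
#' For each anchor length, scores a Monte-Carlo shuffled ensemble with the
#' sliding-window similarity (window `min(L_score, length)`), records the
#' empirical mean and standard deviation, and fits one regression for
#' mu(length) and one for sigma(length) across the anchors. Prediction
#' outside the anchor range clamps to the nearest anchor.
#'
#' @param model an `ngram_model`.
#' @param source a [seq_set] the null ensembles are drawn from (typically the
#'   training set itself).
#' @param L_score scoring window length (capped at each sequence's length).
#' @param anchor_lengths ensemble lengths; default 21, 26, 31, 36 nt,
#'   spanning the piRNA size range in steps of 5.
#' @param ensemble_size sequences per anchor; default 18,000.
#' @param rng_seed integer seed (per-anchor seeds are derived from it).
#' @param regression `"svr"` (epsilon-SVR, RBF kernel; default) or `"lm"`
#'   (quadratic polynomial).
#' @param svr_cost,svr_epsilon epsilon-SVR hyperparameters.
#' @return An object of class `z_calibration`.
#' @export
calibrate <- function(model, source, L_score,
                      anchor_lengths = c(21L, 26L, 31L, 36L),
                      ensemble_size = 18000L, rng_seed = 1L,
                      regression = c("svr", "lm"),
                      svr_cost = 10, svr_epsilon = 0.01) {
  regression <- match.arg(regression)
  anchor_lengths <- sort(as.integer(anchor_lengths))
  if (any(anchor_lengths < model$n)) {
    stop("anchor lengths must be >= model n", call. = FALSE)
  }
  if (L_score < model$n) stop("L_score must be >= model n", call. = FALSE)
  mu_at <- numeric(length(anchor_lengths))
  sigma_at <- numeric(length(anchor_lengths))
  for (i in seq_along(anchor_lengths)) {
    l <- anchor_lengths[i]
    ens <- build_ensemble(source, l, ensemble_size,
                          derive_seed(rng_seed, i))
    s <- scan_set_similarity(model, ens, min(L_score, l))
    mu_at[i] <- mean(s)
    sigma_at[i] <- stats::sd(s)
    if (!is.finite(sigma_at[i]) || sigma_at[i] < 1e-12) {
      stop("degenerate null ensemble: sigma ~ 0 at anchor length ", l,
           call. = FALSE)
    }
  }
  cal <- structure(list(
    model_id = NULL,
    anchor_lengths = anchor_lengths,
    mu_at = stats::setNames(mu_at, anchor_lengths),
    sigma_at = stats::setNames(sigma_at, anchor_lengths),
    L_score = as.integer(L_score),
    ensemble_size = as.integer(ensemble_size),
    rng_seed = as.integer(rng_seed),
    regression = regression,
    svr_cost = svr_cost,
    svr_epsilon = svr_epsilon
  ), class = "z_calibration")
  rebuild_predictors(cal)
}

# (Re)fit the mu/sigma curves from the stored anchor table. Fitting is
# deterministic, so a calibration restored from its serialized anchors is
# identical to the original.
rebuild_predictors <- function(cal) {
  cal$mu_fit <- .fit_curve(cal$anchor_lengths, unname(cal$mu_at),
                           cal$regression, cal$svr_cost, cal$svr_epsilon)
  cal$sigma_fit <- .fit_curve(cal$anchor_lengths, unname(cal$sigma_at),
                              cal$regression, cal$svr_cost, cal$svr_epsilon)
  cal
}

#' Predicted null mean and standard deviation at a given length
#'
#' Lengths outside the anchor range are clamped to the nearest anchor before
#' prediction (extrapolation by clamping).
#'
#' @param cal a `z_calibration`.
#' @param len sequence length(s).
#' @return Numeric vector of predicted values.
#' @export
mu_predict <- function(cal, len) {
  z <- pmin(pmax(len, min(cal$anchor_lengths)), max(cal$anchor_lengths))
  cal$mu_fit(z)
}

#' @rdname mu_predict
#' @export
sigma_predict <- function(cal, len) {
  z <- pmin(pmax(len, min(cal$anchor_lengths)), max(cal$anchor_lengths))
  cal$sigma_fit(z)
}

#' Z-score of a sequence against a calibrated model
#'
#' Computes `(S - mu(len)) / sigma(len)` where `S` is the max-over-windows
#' similarity of the sequence under `model` (window `min(L_score,
#' nchar(seq))`) and mu, sigma come from the calibration's length regressions.
#'
#' @param cal a `z_calibration` built for `model`.
#' @param model the `ngram_model` the calibration belongs to.
#' @param seq a single character string over \{A,C,G,T\}.
#' @param L_score scoring window length; defaults to the calibration's own.
#' @return The Z-score (single numeric).
#' @export
zscore <- function(cal, model, seq, L_score = cal$L_score) {
  len <- nchar(seq)
  s <- scan_max_similarity(model, seq, min(L_score, len))$value
  sig <- sigma_predict(cal, len)
  if (sig <= 0) stop("predicted sigma <= 0 at length ", len, call. = FALSE)
  (s - mu_predict(cal, len)) / sig
}

# Vectorised zscore over a seq_set (one model/calibration, many sequences).
zscore_set <- function(cal, model, x, L_score = cal$L_score) {
  len <- nchar(x$seq)
  s <- scan_set_similarity(model, x, L_score)
  sig <- sigma_predict(cal, len)
  if (any(sig <= 0)) stop("predicted sigma <= 0", call. = FALSE)
  stats::setNames((s - mu_predict(cal, len)) / sig, x$id)
}

#' @export
print.z_calibration <- function(x, ...) {
  cat(sprintf("<z_calibration> anchors %s nt, ensemble %d, regression '%s'\n",
              paste(x$anchor_lengths, collapse = "/"), x$ensemble_size,
              x$regression))
  cat(sprintf("  mu:    %s\n", paste(sprintf("%.2f", x$mu_at), collapse = " ")))
  cat(sprintf("  sigma: %s\n", paste(sprintf("%.2f", x$sigma_at), collapse = " ")))
  invisible(x)
}
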