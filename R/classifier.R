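# NGM feature extraction and the SVM piRNA detector.
#
# Each classified family contributes one feature per sequence: the Z-score of
# the sequence's similarity to the family's n-gram model. A c-classification
# SVM with an RBF kernel separates piRNAs from background in this (typically
# small, < 50-dimensional) feature space; confidence probabilities come from
# a logistic (Platt-style) map fitted on the training decision values, which
# keeps prediction fully deterministic.

#' Z-score feature matrix for a set of sequences
#'
#' One column per family, in discovery order; one row per sequence, in input
#' order. Each entry is the sequence's Z-score against that family's model,
#' using the family's detection-stage calibration when present and its
#' clustering-stage scalar null otherwise. The scoring window is
#' `min(L_score, nchar(seq))`.
#'
#' @param families non-empty list of `sequence_family` objects.
#' @param seqs a [seq_set].
#' @param L_score scoring window length.
#' @return Numeric matrix (`length(seqs)` x `length(families)`), rownames =
#'   sequence ids.
#' @export
featurize <- function(families, seqs, L_score) {
  if (length(families) == 0L) stop("no families: cannot build features",
                                   call. = FALSE)
  cols <- lapply(families, function(f) {
    if (!is.null(f$calibration)) {
      zscore_set(f$calibration, f$model, seqs, L_score)
    } else {
      s <- scan_set_similarity(f$model, seqs, L_score)
      (s - f$null$mu) / f$null$sigma
    }
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(seqs$id,
                      sprintf("fam%d", vapply(families, function(f)
                        as.integer(f$family_id), integer(1))))
  m
}

# Platt-style sigmoid: logistic regression of the 0/1 label on the SVM
# decision value, oriented so larger output means "piRNA".
.fit_platt <- function(decision, y01) {
  fit <- suppressWarnings(
    stats::glm(y01 ~ d, data = data.frame(d = decision, y01 = y01),
               family = stats::binomial()))
  unname(stats::coef(fit))
}

.platt_prob <- function(coefs, decision) {
  stats::plogis(coefs[1L] + coefs[2L] * decision)
}

#' Train the NGM-feature piRNA detector
#'
#' Clusters the positive training sequences into homologous families, builds
#' a detection-stage multi-length Z calibration for each family model (null
#' ensembles are shuffles of the positive training set), featurizes positives
#' and negatives, and fits an RBF-kernel c-classification SVM with a logistic
#' confidence map. Training is deterministic given the seeds in `params` /
#' `svm_config`.
#'
#' @param pos positive training sequences (known piRNAs), a [seq_set].
#' @param neg negative training sequences, a [seq_set].
#' @param params [clustering_params] for the family-clustering stage.
#' @param svm_config list of classifier settings; recognised entries:
#'   `cost` (default 1), `gamma` (default `1 / (n_features * var(features))`),
#'   `grid_search` (default `FALSE`; internal 3-fold CV over
#'   `cost in {0.1, 1, 10}`, `gamma in {0.01, 0.1, 1}`),
#'   `anchor_lengths` (default 21/26/31/36), `ensemble_size` (detection-stage
#'   null size, default 18,000), `regression` (`"svr"` or `"lm"`),
#'   `rng_seed`.
#' @return An object of class `pirna_detector`.
#' @export
train_detector <- function(pos, neg, params = clustering_params(),
                           svm_config = list()) {
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("positive and negative training sets must be non-empty",
         call. = FALSE)
  }
  cfg <- utils::modifyList(list(cost = 1, gamma = NULL, grid_search = FALSE,
                                anchor_lengths = c(21L, 26L, 31L, 36L),
                                ensemble_size = 18000L,
                                regression = "svr", rng_seed = 1L),
                           svm_config)
  clus <- cluster_all(pos, params)
  families <- clus$families
  if (length(families) == 0L) {
    stop("no homologous families found; the dataset may be too small to ",
         "build n-gram models - try a smaller N_th or more training data",
         call. = FALSE)
  }
  L_score <- if (is.null(params$L)) min_length(pos) else params$L
  for (i in seq_along(families)) {
    families[[i]]$calibration <- calibrate(
      families[[i]]$model, pos, L_score,
      anchor_lengths = cfg$anchor_lengths,
      ensemble_size = cfg$ensemble_size,
      rng_seed = derive_seed(cfg$rng_seed, 1000L + i),
      regression = cfg$regression)
  }
  x <- rbind(featurize(families, pos, L_score),
             featurize(families, neg, L_score))
  y <- factor(c(rep("piRNA", length(pos)), rep("non-piRNA", length(neg))),
              levels = c("non-piRNA", "piRNA"))
  if (is.null(cfg$gamma)) {
    v <- stats::var(as.vector(x))
    cfg$gamma <- 1 / (ncol(x) * max(v, 1e-8))
  }
  if (isTRUE(cfg$grid_search)) {
    sel <- .svm_grid_search(x, y, cfg$rng_seed)
    cfg$cost <- sel$cost
    cfg$gamma <- sel$gamma
  }
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = cfg$cost, gamma = cfg$gamma,
                    scale = FALSE)
  dec <- .decision_pirna(fit, x)
  platt <- .fit_platt(dec, as.integer(y == "piRNA"))
  structure(list(families = families, svm = fit, platt = platt,
                 L_score = L_score, n = params$n, params = params,
                 svm_config = cfg,
                 training = list(x = x, y = y),
                 training_meta = list(n_pos = length(pos),
                                      n_neg = length(neg),
                                      n_families = length(families),
                                      rng_seed = cfg$rng_seed)),
            class = "pirna_detector")
}

# decision values oriented so positive = "piRNA"
.decision_pirna <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  d <- attr(p, "decision.values")
  sgn <- if (grepl("^piRNA/", colnames(d)[1L])) 1 else -1
  sgn * as.numeric(d[, 1L])
}

.svm_grid_search <- function(x, y, rng_seed,
                             costs = c(0.1, 1, 10),
                             gammas = c(0.01, 0.1, 1)) {
  folds <- withr::with_seed(rng_seed,
                            sample(rep_len(1:3, nrow(x))))
  best <- list(acc = -1, cost = 1, gamma = 0.1)
  for (co in costs) for (ga in gammas) {
    acc <- mean(vapply(1:3, function(k) {
      fit <- e1071::svm(x = x[folds != k, , drop = FALSE], y = y[folds != k],
                        type = "C-classification", kernel = "radial",
                        cost = co, gamma = ga, scale = FALSE)
      mean(stats::predict(fit, x[folds == k, , drop = FALSE]) == y[folds == k])
    }, numeric(1)))
    if (acc > best$acc) best <- list(acc = acc, cost = co, gamma = ga)
  }
  best
}

#' @export
print.pirna_detector <- function(x, ...) {
  cat(sprintf("<pirna_detector> %d families, n=%d, window L=%d, SVM cost=%g gamma=%g\n",
              length(x$families), x$n, x$L_score, x$svm_config$cost,
              x$svm_config$gamma))
  invisible(x)
}

#' Predict piRNAs with a trained detector
#'
#' @param object a `pirna_detector`.
#' @param seqs a [seq_set] of candidate sequences.
#' @param threshold decision threshold on the confidence probability
#'   (default 0.5); lowering/raising it traces the ROC curve.
#' @param ... unused.
#' @return A data frame with columns `id`, `label` (`"piRNA"` /
#'   `"non-piRNA"`), `confidence` (in \[0,1\]), in input order. Sequences
#'   shorter than the model's gram size get `NA` label/confidence with a
#'   warning; the rest are still processed.
#' @export
predict.pirna_detector <- function(object, seqs, threshold = 0.5, ...) {
  ok <- nchar(seqs$seq) >= object$n
  if (!all(ok)) {
    warning(sum(!ok), " sequence(s) shorter than n=", object$n,
            " skipped: ", paste(utils::head(seqs$id[!ok], 3L),
                                collapse = ", "), call. = FALSE)
  }
  conf <- rep(NA_real_, length(seqs))
  if (any(ok)) {
    x <- featurize(object$families, seqs[ok], object$L_score)
    dec <- .decision_pirna(object$svm, x)
    conf[ok] <- .platt_prob(object$platt, dec)
  }
  data.frame(id = seqs$id,
             label = ifelse(is.na(conf), NA_character_,
                            ifelse(conf >= threshold, "piRNA", "non-piRNA")),
             confidence = conf,
             stringsAsFactors = FALSE)
}

#' Save / load a detector model bundle
#'
#' The bundle is a directory of plain-text documents: a manifest with the
#' resolved configuration and seeds, a family membership table, one JSON
#' model document per family (n-gram tables plus calibration anchors), and
#' the SVM's training matrix and hyperparameters. On load the calibration
#' regressions and the SVM are refit from these inputs; the fits are
#' deterministic, so `predict()` on a reloaded bundle reproduces the original
#' predictions exactly.
#'
#' @param model a `pirna_detector`.
#' @param dir bundle directory (created if missing).
#' @return `save_detector()`: `dir`, invisibly; `load_detector()`: the
#'   restored `pirna_detector`.
#' @export
save_detector <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(family_table(model$families),
                     file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (f in model$families) {
    write_ngm(f$model, file.path(dir, sprintf("family_%d_model.json",
                                              f$family_id)))
    cal <- f$calibration
    jsonlite::write_json(
      list(anchor_lengths = cal$anchor_lengths,
           mu_at = unname(cal$mu_at), sigma_at = unname(cal$sigma_at),
           L_score = cal$L_score, ensemble_size = cal$ensemble_size,
           rng_seed = cal$rng_seed, regression = cal$regression,
           svr_cost = cal$svr_cost, svr_epsilon = cal$svr_epsilon),
      file.path(dir, sprintf("family_%d_calibration.json", f$family_id)),
      auto_unbox = TRUE, digits = I(17))
  }
  jsonlite::write_json(
    list(package = "pirnangm",
         version = as.character(utils::packageVersion("pirnangm")),
         n = model$n, L_score = model$L_score,
         family_ids = vapply(model$families, function(f)
           as.integer(f$family_id), integer(1)),
         seed_ids = vapply(model$families, function(f) f$seed_id,
                           character(1)),
         platt = model$platt,
         svm_config = model$svm_config[c("cost", "gamma")],
         params = unclass(model$params)[c("n", "Z_th", "N_th",
                                          "pseudo_count", "ensemble_size",
                                          "rng_seed")],
         training_meta = model$training_meta,
         y = as.character(model$training$y)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = I(17))
  # %.17g keeps the feature matrix bit-exact through the text round trip
  xfmt <- apply(model$training$x, c(1L, 2L), sprintf, fmt = "%.17g")
  utils::write.table(
    data.frame(id = rownames(model$training$x), xfmt, check.names = FALSE),
    file.path(dir, "training_features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' @rdname save_detector
#' @export
load_detector <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fam_tab <- utils::read.delim(file.path(dir, "families.tsv"),
                               stringsAsFactors = FALSE)
  families <- lapply(seq_along(man$family_ids), function(i) {
    fid <- man$family_ids[i]
    cal_doc <- jsonlite::read_json(
      file.path(dir, sprintf("family_%d_calibration.json", fid)),
      simplifyVector = TRUE)
    cal <- structure(list(
      model_id = NULL,
      anchor_lengths = as.integer(cal_doc$anchor_lengths),
      mu_at = stats::setNames(cal_doc$mu_at, cal_doc$anchor_lengths),
      sigma_at = stats::setNames(cal_doc$sigma_at, cal_doc$anchor_lengths),
      L_score = as.integer(cal_doc$L_score),
      ensemble_size = as.integer(cal_doc$ensemble_size),
      rng_seed = as.integer(cal_doc$rng_seed),
      regression = cal_doc$regression,
      svr_cost = cal_doc$svr_cost,
      svr_epsilon = cal_doc$svr_epsilon), class = "z_calibration")
    structure(list(family_id = fid, seed_id = man$seed_ids[i],
                   member_ids = fam_tab$member_id[fam_tab$family_id == fid],
                   model = read_ngm(file.path(
                     dir, sprintf("family_%d_model.json", fid))),
                   null = NULL, L = man$L_score,
                   calibration = rebuild_predictors(cal)),
              class = "sequence_family")
  })
  feat <- utils::read.delim(file.path(dir, "training_features.tsv"),
                            stringsAsFactors = FALSE, check.names = FALSE)
  x <- as.matrix(feat[, -1L, drop = FALSE])
  rownames(x) <- feat$id
  y <- factor(man$y, levels = c("non-piRNA", "piRNA"))
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = man$svm_config$cost,
                    gamma = man$svm_config$gamma, scale = FALSE)
  params <- do.call(clustering_params,
                    as.list(man$params[c("n", "Z_th", "N_th", "pseudo_count",
                                         "ensemble_size", "rng_seed")]))
  structure(list(families = families, svm = fit, platt = man$platt,
                 L_score = as.integer(man$L_score), n = as.integer(man$n),
                 params = params,
                 svm_config = utils::modifyList(
                   list(grid_search = FALSE), man$svm_config),
                 training = list(x = x, y = y),
                 training_meta = man$training_meta),
            class = "pirna_detector")
}
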