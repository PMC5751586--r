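# End-to-end detector tests run on a small fixture with scaled-down null
# ensembles so the whole file stays fast; ensemble sizes are config.

small_detector <- function() {
  fx <- tiny_fixture()
  params <- clustering_params(N_th = 25L, Z_th = 1.5, ensemble_size = 300,
                              rng_seed = 2)
  det <- train_detector(fx$positives, fx$background, params,
                        svm_config = list(ensemble_size = 300, rng_seed = 3))
  list(fx = fx, det = det)
}

test_that("featurize has the documented shape and orientation", {
  w <- small_detector()
  seqs <- w$fx$positives[1:5]
  x <- featurize(w$det$families, seqs, w$det$L_score)
  expect_identical(dim(x), c(5L, length(w$det$families)))
  expect_identical(rownames(x), seqs$id)
  expect_error(featurize(list(), seqs, 26), "no families")
})

test_that("family members score high against their own family", {
  w <- small_detector()
  fam <- w$det$families[[1]]
  members <- c(w$fx$positives, w$fx$background)[fam$member_ids]
  x <- featurize(list(fam), members, w$det$L_score)
  expect_gte(mean(x[, 1]), 1.5)  # mean member Z at or above Z_th
})

test_that("shuffled background features are approximately standardized", {
  w <- small_detector()
  nulls <- build_ensemble(w$fx$positives, 26, 1000, rng_seed = 77)
  x <- featurize(w$det$families, nulls, w$det$L_score)
  # the ideal bound is 0.1 at full calibration ensembles (18,000); the
  # small_detector calibrates on 300 draws per anchor, so Monte-Carlo noise
  # in the anchors themselves widens the tolerance to 0.25
  expect_true(all(abs(colMeans(x)) <= 0.25))
})

test_that("the detector predicts deterministically with valid confidences", {
  w <- small_detector()
  test <- c(w$fx$positives[1:20], w$fx$background[1:20])
  p1 <- predict(w$det, test)
  p2 <- predict(w$det, test)
  expect_identical(p1, p2)
  expect_identical(p1$id, test$id)
  expect_true(all(p1$confidence >= 0 & p1$confidence <= 1))
  expect_identical(p1$label, ifelse(p1$confidence >= 0.5,
                                    "piRNA", "non-piRNA"))
  # fixture is largely separable: most training sequences classify correctly
  truth <- c(rep("piRNA", 20), rep("non-piRNA", 20))
  expect_gte(mean(p1$label == truth), 0.8)
})

test_that("raising the threshold never increases positive calls", {
  w <- small_detector()
  test <- c(w$fx$positives[1:30], w$fx$background[1:30])
  calls <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    sum(predict(w$det, test, threshold = th)$label == "piRNA"), integer(1))
  expect_true(all(diff(calls) <= 0L))
})

test_that("sequences shorter than n get NA with a warning", {
  w <- small_detector()
  test <- c(seq_set("tiny", "ACG"), w$fx$positives[1:2])
  expect_warning(p <- predict(w$det, test), "shorter")
  expect_true(is.na(p$confidence[1]) && is.na(p$label[1]))
  expect_false(anyNA(p$confidence[-1]))
})

test_that("feature count stays small (one per family, under 50)", {
  w <- small_detector()
  expect_lte(length(w$det$families), 50L)
  x <- featurize(w$det$families, w$fx$positives[1:3], w$det$L_score)
  expect_identical(ncol(x), length(w$det$families))
})

test_that("training is deterministic under identical seeds", {
  fx <- tiny_fixture()
  params <- clustering_params(N_th = 25L, ensemble_size = 300, rng_seed = 2)
  cfg <- list(ensemble_size = 300, rng_seed = 3)
  d1 <- train_detector(fx$positives, fx$background, params, cfg)
  d2 <- train_detector(fx$positives, fx$background, params, cfg)
  test <- c(fx$positives[1:10], fx$background[1:10])
  expect_identical(predict(d1, test), predict(d2, test))
})

test_that("the detector bundle round-trips through save/load", {
  w <- small_detector()
  dir <- withr::local_tempdir()
  save_detector(w$det, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "families.tsv")))
  det2 <- load_detector(dir)
  test <- c(w$fx$positives[1:20], w$fx$background[1:20])
  expect_equal(predict(det2, test), predict(w$det, test), tolerance = 1e-12)
})

test_that("training fails clearly when no family can be built", {
  fx <- tiny_fixture()
  params <- clustering_params(N_th = 200L, ensemble_size = 200, rng_seed = 2)
  expect_error(train_detector(fx$positives[1:50], fx$background[1:50],
                              params),
               "no homologous families")
  expect_error(train_detector(seq_set(), fx$background, params), "non-empty")
})

test_that("the optional grid search selects from the documented grid", {
  fx <- tiny_fixture()
  params <- clustering_params(N_th = 25L, ensemble_size = 200, rng_seed = 2)
  det <- train_detector(fx$positives, fx$background, params,
                        svm_config = list(ensemble_size = 200, rng_seed = 3,
                                          grid_search = TRUE))
  expect_true(det$svm_config$cost %in% c(0.1, 1, 10))
  expect_true(det$svm_config$gamma %in% c(0.01, 0.1, 1))
})
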