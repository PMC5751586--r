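test_that("confusion counts and metrics match their definitions", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  pred <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  cc <- confusion_counts(truth, pred)
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
  m <- metrics(cc)
  expect_equal(unname(m["ACC"]), 3 / 5)
  expect_equal(unname(m["TPR"]), 2 / 3)
  expect_equal(unname(m["FPR"]), 1 / 2)
  # label input
  cc2 <- confusion_counts(c("piRNA", "non-piRNA"), c("piRNA", "piRNA"))
  expect_identical(cc2$TP, 1L)
  expect_identical(cc2$FP, 1L)
})

test_that("metrics error on undefined denominators", {
  expect_error(metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "ACC")
  expect_error(metrics(list(TP = 0, TN = 1, FP = 1, FN = 0)), "TPR")
  expect_error(metrics(list(TP = 1, TN = 0, FP = 0, FN = 1)), "FPR")
})

test_that("symmetric confusion gives 0.5 everywhere", {
  m <- metrics(list(TP = 5, FN = 5, TN = 7, FP = 7))
  expect_equal(unname(m), rep(0.5, 3))
})

test_that("metric identities hold against random recomputation", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      truth <- runif(200) < 0.5
      pred <- runif(200) < 0.5
    })
    if (!any(truth) || all(truth)) next
    cc <- confusion_counts(truth, pred)
    expect_identical(cc$TP + cc$FN, sum(truth))
    expect_identical(cc$TN + cc$FP, sum(!truth))
    m <- metrics(cc)
    expect_equal(unname(m["ACC"]), mean(truth == pred), tolerance = 1e-12)
    expect_equal(unname(m["TPR"]), mean(pred[truth]), tolerance = 1e-12)
    expect_equal(unname(m["FPR"]), mean(pred[!truth]), tolerance = 1e-12)
  }
})

test_that("roc_curve is monotone and spans (0,0) to (1,1)", {
  withr::with_seed(3, {
    scores <- c(rnorm(50, 1), rnorm(50))
    labels <- rep(c(TRUE, FALSE), each = 50)
  })
  r <- roc_curve(scores, labels)
  expect_identical(c(r$FPR[1], r$TPR[1]), c(0, 0))
  expect_identical(c(r$FPR[nrow(r)], r$TPR[nrow(r)]), c(1, 1))
  expect_true(all(diff(r$FPR) >= 0) && all(diff(r$TPR) >= 0))
  expect_true(all(diff(r$threshold) <= 0))
})

test_that("auc hits the analytic extremes and handles ties", {
  labels <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(auc(c(rep(1, 5), rep(0, 5)), labels), 1)
  expect_equal(auc(c(rep(0, 5), rep(1, 5)), labels), 0)
  expect_equal(auc(rep(0.7, 10), labels), 0.5)  # all tied
})

test_that("trapezoidal auc equals the rank-statistic formulation", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(20:120, 1)
      labels <- c(TRUE, FALSE, runif(n) < 0.5)
      scores <- round(rnorm(n + 2), sample(c(1, 8), 1))  # some ties
    })
    expect_equal(auc(scores, labels), rank_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("make_negatives matches lengths and composition source", {
  pos <- random_seqs(25, seed = 10, prefix = "p")
  bg <- random_seqs(40, c(30, 80), seed = 11, prefix = "b")
  neg <- make_negatives(pos, bg, rng_seed = 5)
  expect_length(neg, length(pos))
  expect_identical(seq_lengths(neg), seq_lengths(pos))
  expect_identical(neg$id, paste0("neg_", pos$id))
  # reproducible; different seeds differ but keep the length profile
  expect_identical(make_negatives(pos, bg, 5)$seq, neg$seq)
  neg2 <- make_negatives(pos, bg, 6)
  expect_false(identical(neg2$seq, neg$seq))
  expect_identical(seq_lengths(neg2), seq_lengths(pos))
  expect_error(make_negatives(seq_set("x", strrep("A", 99)), bg, 1),
               "length >= 99")
})

test_that("crossvalidate partitions both classes into stratified folds", {
  pos <- random_seqs(23, seed = 1, prefix = "p")
  neg <- random_seqs(19, seed = 2, prefix = "n")
  # deterministic scorer independent of training: hash of the id
  trainer <- function(tp, tn) function(s) {
    stats::setNames(vapply(s$id, function(i)
      utf8ToInt(substr(i, 1, 1)) / 200, numeric(1)), s$id)
  }
  rep_ <- crossvalidate(pos, neg, k = 5, trainer, rng_seed = 3)
  expect_s3_class(rep_, "eval_report")
  expect_identical(nrow(rep_$folds), 5L)
  expect_setequal(rep_$scores$id, c(pos$id, neg$id))   # partition law
  expect_identical(anyDuplicated(rep_$scores$id), 0L)
  per_fold_pos <- table(rep_$scores$fold[rep_$scores$truth])
  expect_lte(diff(range(per_fold_pos)), 1)             # stratification
  expect_equal(rep_$auc_pct, 100 * rep_$auc)
  expect_error(crossvalidate(pos, neg, k = 1, trainer), "k must be")
  expect_error(crossvalidate(pos[1:3], neg, k = 5, trainer), "at least k")
})

test_that("an oracle scorer gets ACC = AUC = 1; random scores hover at 0.5", {
  pos <- random_seqs(100, seed = 4, prefix = "p")
  neg <- random_seqs(100, seed = 5, prefix = "n")
  oracle <- function(tp, tn) function(s)
    stats::setNames(as.numeric(startsWith(s$id, "p")), s$id)
  rep_ <- crossvalidate(pos, neg, k = 5, oracle, rng_seed = 1)
  expect_equal(rep_$ACC, 1)
  expect_equal(rep_$auc, 1)

  pos2 <- random_seqs(1000, seed = 6, prefix = "p")
  neg2 <- random_seqs(1000, seed = 7, prefix = "n")
  noise <- function(tp, tn) {
    counter <- 0
    function(s) {
      counter <<- counter + 1
      withr::with_seed(counter + 1000L,
                       stats::setNames(runif(length(s)), s$id))
    }
  }
  rep2 <- crossvalidate(pos2, neg2, k = 5, noise, rng_seed = 2)
  expect_gte(rep2$auc, 0.45); expect_lte(rep2$auc, 0.55)
  expect_gte(rep2$ACC, 0.47); expect_lte(rep2$ACC, 0.53)
})

test_that("the NGM and k-mer trainers plug into crossvalidate", {
  fx <- tiny_fixture()
  rep_ <- crossvalidate(fx$positives, fx$background, k = 2,
                        trainer = kmer_trainer(), rng_seed = 1)
  expect_gte(rep_$auc, 0.7)
  params <- clustering_params(N_th = 20L, ensemble_size = 200, rng_seed = 2)
  rep2 <- crossvalidate(fx$positives, fx$background, k = 2,
                        trainer = ngm_trainer(params,
                                              list(ensemble_size = 200,
                                                   rng_seed = 3)),
                        rng_seed = 1)
  expect_gte(rep2$auc, 0.7)
})

test_that("parameter_sweep fills its grid and flags family-free cells", {
  fx <- tiny_fixture()
  params <- clustering_params(ensemble_size = 200, rng_seed = 2)
  tab <- parameter_sweep(fx$positives, fx$background,
                         sizes = c(40L, 120L), N_th_values = c(15L, 500L),
                         Z_th_values = 1.5, params = params,
                         svm_config = list(ensemble_size = 200, rng_seed = 3),
                         k = 2L, rng_seed = 4)
  expect_identical(nrow(tab), 4L)  # |sizes| x |N_th| x |Z_th|
  expect_named(tab, c("size", "N_th", "Z_th", "ACC", "AUC", "families"))
  # N_th beyond the dataset size -> zero families, NA accuracy
  over <- tab$N_th == 500L
  expect_true(all(tab$families[over] == 0))
  expect_true(all(is.na(tab$ACC[over])))
  expect_true(any(tab$families[!over] > 0))
})
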