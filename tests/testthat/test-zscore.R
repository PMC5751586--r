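test_that("build_ensemble honors length, size and composition contracts", {
  src <- random_seqs(30, seed = 2)
  ens <- build_ensemble(src, 21, 50, rng_seed = 7)
  expect_length(ens, 50L)
  expect_true(all(nchar(ens$seq) == 21L))
  expect_false(any(grepl("[^ACGT]", ens$seq)))
  # determinism
  ens2 <- build_ensemble(src, 21, 50, rng_seed = 7)
  expect_identical(ens2$seq, ens$seq)
  expect_false(identical(build_ensemble(src, 21, 50, rng_seed = 8)$seq,
                         ens$seq))
  # every output is a permutation of a window of some source sequence: its
  # base multiset appears as a window multiset in at least one source record
  sorted <- vapply(strsplit(ens$seq, ""), function(ch)
    paste(sort(ch), collapse = ""), character(1))
  window_multisets <- unique(unlist(lapply(src$seq, function(s) {
    starts <- seq_len(nchar(s) - 21L + 1L)
    vapply(starts, function(k)
      paste(sort(strsplit(substr(s, k, k + 20L), "")[[1L]]), collapse = ""),
      character(1))
  })))
  expect_true(all(sorted %in% window_multisets))
})

test_that("build_ensemble rejects impossible requests", {
  src <- random_seqs(5, c(26, 30), seed = 1)
  expect_error(build_ensemble(src, 40, 10, 1), "length >= 40")
  expect_error(build_ensemble(src, 21, 1, 1), "size")
  expect_error(build_ensemble(seq_set(), 21, 10, 1), "empty")
})

test_that("calibrate errors on the degenerate uniform model", {
  # every window of every sequence scores identically -> sigma = 0
  expect_error(calibrate(uniform_model(4), random_seqs(20, seed = 3), 21,
                         ensemble_size = 50, rng_seed = 1),
               "degenerate")
})

test_that("calibration is reproducible and anchored to its ensembles", {
  fx <- tiny_fixture()
  model <- fit_ngm(fx$positives[1:60], n = 4)
  cal <- calibrate(model, fx$positives, 26, ensemble_size = 500, rng_seed = 4)
  cal2 <- calibrate(model, fx$positives, 26, ensemble_size = 500, rng_seed = 4)
  expect_identical(cal$mu_at, cal2$mu_at)
  expect_identical(cal$sigma_at, cal2$sigma_at)

  # anchored-regression tolerance: predictions reproduce the empirical
  # anchor statistics within 0.05 * |value| + 0.5
  for (l in cal$anchor_lengths) {
    key <- as.character(l)
    expect_lte(abs(mu_predict(cal, l) - cal$mu_at[[key]]),
               0.05 * abs(cal$mu_at[[key]]) + 0.5)
    expect_lte(abs(sigma_predict(cal, l) - cal$sigma_at[[key]]),
               0.05 * abs(cal$sigma_at[[key]]) + 0.5)
  }

  # mu decreases with length when the scoring window grows with it
  mus <- unname(unlist(cal$mu_at))
  expect_true(all(diff(mus[1:2]) < 0))  # 21 -> 26: window itself grows
})

test_that("prediction clamps outside the anchor range", {
  fx <- tiny_fixture()
  model <- fit_ngm(fx$positives[1:60], n = 4)
  cal <- calibrate(model, fx$positives, 26, ensemble_size = 300, rng_seed = 4)
  expect_identical(mu_predict(cal, 10), mu_predict(cal, 21))
  expect_identical(mu_predict(cal, 99), mu_predict(cal, 36))
  expect_identical(sigma_predict(cal, 10), sigma_predict(cal, 21))
})

test_that("constant anchor values are recovered by both regressions", {
  fx <- tiny_fixture()
  model <- fit_ngm(fx$positives[1:60], n = 4)
  for (reg in c("svr", "lm")) {
    cal <- calibrate(model, fx$positives, 26, ensemble_size = 300,
                     rng_seed = 4, regression = reg)
    cal$mu_at[] <- -30  # force a constant curve, then refit
    cal$sigma_at[] <- 2
    cal <- pirnangm:::rebuild_predictors(cal)
    for (l in cal$anchor_lengths) {
      expect_lte(abs(mu_predict(cal, l) - (-30)), 0.05 * 30 + 0.5)
      expect_lte(abs(sigma_predict(cal, l) - 2), 0.05 * 2 + 0.5)
    }
  }
})

test_that("zscore standardizes: Z at the mean is 0, one sigma above is 1", {
  fx <- tiny_fixture()
  model <- fit_ngm(fx$positives[1:60], n = 4)
  cal <- calibrate(model, fx$positives, 26, ensemble_size = 300, rng_seed = 4)
  s <- fx$positives$seq[1]
  z <- zscore(cal, model, s)
  raw <- scan_max_similarity(model, s, min(26L, nchar(s)))$value
  mu <- mu_predict(cal, nchar(s))
  sig <- sigma_predict(cal, nchar(s))
  expect_equal(z, (raw - mu) / sig, tolerance = 1e-12)
  # synthetic check of the identity itself
  expect_equal((mu - mu) / sig, 0)
  expect_equal(((mu + sig) - mu) / sig, 1)
})

test_that("a fresh null ensemble standardizes to mean 0, sd 1", {
  fx <- tiny_fixture()
  model <- fit_ngm(fx$positives[1:60], n = 4)
  cal <- calibrate(model, fx$positives, 26, ensemble_size = 2000, rng_seed = 4)
  fresh <- build_ensemble(fx$positives, 26, 2000, rng_seed = 99)
  s <- vapply(fresh$seq, function(x)
    scan_max_similarity(model, x, 26)$value, numeric(1), USE.NAMES = FALSE)
  z <- (s - cal$mu_at[["26"]]) / cal$sigma_at[["26"]]
  expect_gte(mean(z), -0.1); expect_lte(mean(z), 0.1)
  expect_gte(sd(z), 0.9); expect_lte(sd(z), 1.1)
})

test_that("family members separate from the null by >= 2 Z units", {
  fx <- tiny_fixture()
  fam1 <- fx$positives[1:60]
  model <- fit_ngm(fam1, n = 4)
  cal <- calibrate(model, fx$positives, 26, ensemble_size = 1000, rng_seed = 4)
  z_members <- vapply(seq_along(fam1$id), function(i)
    zscore(cal, model, fam1$seq[i]), numeric(1))
  nulls <- build_ensemble(fx$positives, 26, 500, rng_seed = 41)
  z_null <- vapply(nulls$seq, function(s) zscore(cal, model, s), numeric(1),
                   USE.NAMES = FALSE)
  expect_gte(mean(z_members) - mean(z_null), 2)
})
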