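# Shared helpers for the test suite: small deterministic sequence sets,
# reference oracles, and a tiny reusable fixture.

random_seqs <- function(n, len_range = c(26L, 36L), seed = 1L, prefix = "s") {
  withr::with_seed(seed, {
    lens <- len_range[1L] -1L +
      sample.int(len_range[2L] - len_range[1L] + 1L, n, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), character(1))
  })
  seq_set(sprintf("%s%04d", prefix, seq_len(n)), seqs)
}

# A small two-family fixture used by several module tests: quick to cluster,
# structured enough that families are recoverable.
tiny_fixture <- function(seed = 1L) {
  generate_fixture(fixture_spec(num_families = 2L, family_size = 60L,
                                background_size = 80L, rng_seed = seed))
}

# Naive reference for scan_max_similarity: rescore every window from scratch.
naive_scan <- function(model, seq, L) {
  offsets <- 0:(nchar(seq) - L)
  vals <- vapply(offsets, function(k) loglik_window(model, seq, k, L),
                 numeric(1))
  list(value = max(vals), offset = offsets[which.max(vals)], all = vals)
}

# Mann-Whitney rank-statistic AUC: P(score_pos > score_neg) + 0.5 P(tie).
rank_auc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Fraction of planted positives recovered by a clustering, and the fraction
# of family members that are background, from a fixture truth map.
family_recovery <- function(families, truth) {
  member_ids <- unlist(lapply(families, `[[`, "member_ids"))
  planted <- names(truth)[truth != "background"]
  list(recovery = mean(planted %in% member_ids),
       contamination = if (length(member_ids) == 0L) 0 else
         mean(truth[member_ids] == "background"))
}
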