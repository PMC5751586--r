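# Seed-and-collect clustering of piRNAs into motif-sharing families.
#
# A subset of piRNAs derives from genomic repeats and therefore shares
# sequence motifs. The clustering exploits this: the sequence carrying the
# most frequent (n-1)-gram in the pool seeds an n-gram model; every pool
# sequence is Z-scored against that model (null: shuffled pool sequences at
# the dataset minimum length L); sequences with Z >= Z_th form a family if at
# least N_th of them pass. Collected families are removed from the pool and
# the procedure repeats until every remaining sequence has been tried as a
# seed.

#' Clustering parameters
#'
#' @param n gram size (default 4, the tetragram).
#' @param Z_th Z-score threshold for family membership (default 1.5).
#' @param N_th minimum family size (default 200). The pair
#'   `(N_th, Z_th) = (200, 1.5)` balances accuracy against the number of
#'   models built.
#' @param pseudo_count additive smoothing alpha for all fitted models.
#' @param L scoring window length; `NULL` (default) means the minimum
#'   sequence length of the full dataset, fixed once per clustering run so
#'   all families score on one scale.
#' @param ensemble_size clustering-stage null ensemble size (default 2,000;
#'   this null is rebuilt at every seed attempt).
#' @param rng_seed integer seed for the null ensembles.
#' @param seed_criterion how the seed is chosen: `"pool-max-gram"` (default)
#'   scores each sequence by the pool-wide count of the most frequent
#'   (n-1)-gram it contains; `"self-weighted"` sums the pool-wide counts of
#'   all its gram occurrences.
#' @param refine_iterations number of refit-and-recollect refinement passes
#'   after the seed pass (default 3). A model fitted on a single 26-36 nt
#'   seed is too diffuse to pull in most true relatives of a degenerate
#'   motif; refitting on the collected members and re-thresholding raises
#'   recall, in the manner of iterative profile searches. To prevent profile
#'   drift (false inclusions near the threshold dragging a second motif into
#'   the family), each refit uses only the members at or above the member
#'   median Z. `0` reproduces the plain single-pass seed collection.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(n = 4L, Z_th = 1.5, N_th = 200L,
                              pseudo_count = 1, L = NULL,
                              ensemble_size = 2000L, rng_seed = 1L,
                              seed_criterion = c("pool-max-gram",
                                                 "self-weighted"),
                              refine_iterations = 3L) {
  if (N_th < 1L) stop("N_th must be >= 1", call. = FALSE)
  if (refine_iterations < 0L) stop("refine_iterations must be >= 0",
                                   call. = FALSE)
  structure(list(n = as.integer(n), Z_th = Z_th, N_th = as.integer(N_th),
                 pseudo_count = pseudo_count,
                 L = if (is.null(L)) NULL else as.integer(L),
                 ensemble_size = as.integer(ensemble_size),
                 rng_seed = as.integer(rng_seed),
                 seed_criterion = match.arg(seed_criterion),
                 refine_iterations = as.integer(refine_iterations)),
            class = "clustering_params")
}

#' @rdname clustering_params
#' @export
print.clustering_params <- function(x, ...) {
  cat(sprintf("<clustering_params> n=%d Z_th=%g N_th=%d alpha=%g ensemble=%d refine=%d\n",
              x$n, x$Z_th, x$N_th, x$pseudo_count, x$ensemble_size,
              x$refine_iterations))
  invisible(x)
}

#' Pick the seed sequence of a pool
#'
#' Tallies every (n-1)-gram across the whole pool and returns the sequence
#' containing the gram with the highest pool-wide count. Ties are broken by
#' the number of occurrences of that gram within the sequence, then by input
#' order.
#'
#' @param pool a [seq_set].
#' @param n gram size.
#' @param exclude ids ineligible for seeding (already tried).
#' @param criterion see [clustering_params].
#' @return The id of the chosen seed.
#' @export
pick_seed <- function(pool, n = 4L, exclude = character(0),
                      criterion = "pool-max-gram") {
  if (length(pool) == 0L) stop("empty pool", call. = FALSE)
  w <- as.integer(n) - 1L
  n_gram <- 4L^w
  per_seq <- lapply(pool$seq, function(s)
    tabulate(gram_indices(encode_seq(s), w), n_gram))
  pool_counts <- Reduce(`+`, per_seq)
  eligible <- which(!(pool$id %in% exclude))
  if (length(eligible) == 0L) stop("no eligible seed candidates",
                                   call. = FALSE)
  if (criterion == "pool-max-gram") {
    score <- vapply(eligible, function(i)
      max(pool_counts[per_seq[[i]] > 0L]), numeric(1))
    tiebreak <- vapply(eligible, function(i) {
      present <- per_seq[[i]] > 0L
      best <- max(pool_counts[present])
      max(per_seq[[i]][present & pool_counts == best])
    }, numeric(1))
  } else {
    score <- vapply(eligible, function(i)
      sum(per_seq[[i]] * pool_counts), numeric(1))
    tiebreak <- rep(0, length(eligible))
  }
  pool$id[eligible[order(-score, -tiebreak, seq_along(eligible))[1L]]]
}

#' Collect a homologous family around a seed
#'
#' Fits an n-gram model on the seed alone, standardises every pool sequence's
#' similarity against a shuffled-pool null at window length `L`, and gathers
#' the sequences with `Z >= Z_th` (the seed always included). The collection
#' is then refined `refine_iterations` times: the model is refit on the upper
#' half of the current members (those at or above the member median Z, which
#' keeps near-threshold false inclusions out of the profile), the null
#' rebuilt for the refit model, and membership re-thresholded at `Z_th`. If
#' at least `N_th` sequences remain at the end, the family is returned with
#' the model refit on all final members and a matching null; otherwise
#' `NULL`.
#'
#' @param pool a [seq_set] containing the seed.
#' @param seed_id id of the seed sequence.
#' @param params a [clustering_params]; its `L` must be set (use
#'   [cluster_all] for the usual dataset-driven default).
#' @param null_seed integer seed for this attempt's null ensembles.
#' @return A `sequence_family` (list with `seed_id`, `member_ids`, `model`,
#'   `null`) or `NULL` if fewer than `N_th` sequences pass.
#' @export
collect_family <- function(pool, seed_id, params,
                           null_seed = params$rng_seed) {
  if (!seed_id %in% pool$id) stop("seed not in pool: ", seed_id,
                                  call. = FALSE)
  L <- params$L
  if (is.null(L)) L <- min_length(pool)
  if (L < params$n) stop("window length L < n", call. = FALSE)
  members <- seed_id
  z <- NULL
  for (it in 0:params$refine_iterations) {
    refit_set <- if (is.null(z)) members else {
      mz <- z[members]
      union(seed_id, members[mz >= stats::median(mz)])
    }
    model <- fit_ngm(pool[refit_set], n = params$n,
                     pseudo_count = params$pseudo_count)
    nul <- null_stats(model, pool, L, params$ensemble_size,
                      derive_seed(null_seed, it))
    s <- scan_set_similarity(model, pool, L)
    z <- (s - nul$mu) / nul$sigma
    members <- union(seed_id, pool$id[z >= params$Z_th])
  }
  if (length(members) < params$N_th) return(NULL)
  model <- fit_ngm(pool[members], n = params$n,
                   pseudo_count = params$pseudo_count)
  nul <- null_stats(model, pool, L, params$ensemble_size,
                    derive_seed(null_seed, params$refine_iterations + 1L))
  structure(list(family_id = NA_integer_, seed_id = seed_id,
                 member_ids = members, model = model, null = nul,
                 L = L, calibration = NULL),
            class = "sequence_family")
}

#' @export
print.sequence_family <- function(x, ...) {
  cat(sprintf("<sequence_family> id=%s seed=%s, %d members, n=%d\n",
              as.character(x$family_id), x$seed_id, length(x$member_ids),
              x$model$n))
  invisible(x)
}

#' Cluster a dataset into homologous families
#'
#' Repeatedly picks the best seed among untried pool sequences and attempts
#' to collect a family around it. A successful family is extracted from the
#' pool; a failed seed is retired from seeding but remains collectible by
#' later families. The loop ends when every remaining sequence has been tried
#' as a seed, so it always terminates: each iteration removes at least `N_th`
#' sequences or retires one candidate.
#'
#' @param dataset a non-empty [seq_set].
#' @param params a [clustering_params]; if its `L` is `NULL` the minimum
#'   sequence length of `dataset` is used throughout the run.
#' @return A list with `families` (list of `sequence_family`, in discovery
#'   order, with `family_id` assigned) and `residual` (the unclassified
#'   [seq_set]).
#' @export
cluster_all <- function(dataset, params = clustering_params()) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(params$L)) params$L <- min_length(dataset)
  pool <- dataset
  tried <- character(0)
  families <- list()
  max_iter <- 2L * length(dataset)
  iter <- 0L
  while (length(pool) > 0L && any(!(pool$id %in% tried))) {
    iter <- iter + 1L
    if (iter > max_iter) stop("clustering failed to terminate", call. = FALSE)
    seed_id <- pick_seed(pool, params$n, exclude = tried,
                         criterion = params$seed_criterion)
    fam <- collect_family(pool, seed_id, params,
                          null_seed = derive_seed(params$rng_seed, iter))
    if (is.null(fam)) {
      tried <- c(tried, seed_id)
    } else {
      fam$family_id <- length(families) + 1L
      families[[length(families) + 1L]] <- fam
      pool <- pool[!(pool$id %in% fam$member_ids)]
      tried <- intersect(tried, pool$id)
    }
  }
  list(families = families, residual = pool)
}

#' Export family membership as a table
#'
#' @param families list of `sequence_family` objects.
#' @return A data frame with columns `family_id`, `seed_id`, `member_id`.
#' @export
family_table <- function(families) {
  if (length(families) == 0L) {
    return(data.frame(family_id = integer(0), seed_id = character(0),
                      member_id = character(0)))
  }
  do.call(rbind, lapply(families, function(f)
    data.frame(family_id = f$family_id, seed_id = f$seed_id,
               member_id = f$member_ids, stringsAsFactors = FALSE)))
}
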