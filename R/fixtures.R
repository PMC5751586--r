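# Ground-truth synthetic data: motif-sharing sequence families plus an
# unrelated background pool.
#
# The generator emulates the statistical structure the detector assumes —
# repeat-derived piRNA families sharing a degenerate motif — without any
# database download. Each family has a random motif template; members embed a
# point-mutated copy of it at a random offset inside random flanking
# sequence. Background sequences are i.i.d. draws from a base-composition
# model. Motifs are embedded (rather than making whole sequences homologous)
# so the max-over-windows scan is genuinely exercised.

#' Specification of a synthetic fixture
#'
#' @param num_families number of planted motif families.
#' @param family_size sequences per family.
#' @param motif_length length of each family's motif template (default 12 nt).
#' @param length_range inclusive range sequence lengths are drawn from
#'   (default 26-36 nt, the piRNA size range).
#' @param mutation_rate per-base substitution probability applied to each
#'   embedded motif copy (default 0.10; must be in \[0, 0.5\]).
#' @param background_size number of background sequences.
#' @param background_composition base probabilities (A, C, G, T) for
#'   background and flanking sequence (default uniform).
#' @param rng_seed integer seed; generation is fully reproducible from it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(num_families = 2L, family_size = 120L,
                         motif_length = 12L, length_range = c(26L, 36L),
                         mutation_rate = 0.10, background_size = 500L,
                         background_composition = rep(0.25, 4),
                         rng_seed = 1L) {
  if (mutation_rate < 0 || mutation_rate > 0.5) {
    stop("mutation_rate must be in [0, 0.5]", call. = FALSE)
  }
  if (motif_length > min(length_range)) {
    stop("motif_length exceeds the minimum sequence length", call. = FALSE)
  }
  if (num_families < 0L || family_size < 0L || background_size < 0L) {
    stop("sizes must be >= 0", call. = FALSE)
  }
  stopifnot(length(background_composition) == 4,
            all(background_composition >= 0),
            sum(background_composition) > 0)
  structure(list(num_families = as.integer(num_families),
                 family_size = as.integer(family_size),
                 motif_length = as.integer(motif_length),
                 length_range = as.integer(length_range),
                 mutation_rate = mutation_rate,
                 background_size = as.integer(background_size),
                 background_composition =
                   background_composition / sum(background_composition),
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

.random_bases <- function(n, prob) {
  paste(sample(.BASES, n, replace = TRUE, prob = prob), collapse = "")
}

.mutate_motif <- function(motif, rate) {
  if (rate == 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic dataset
#'
#' @param spec a [fixture_spec].
#' @return A list with `positives` (a [seq_set] of all family members),
#'   `background` (a [seq_set]), and `truth` (named character vector mapping
#'   every id to its family label, e.g. `"fam1"`, or `"background"`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$rng_seed, {
    comp <- spec$background_composition
    pos_id <- character(0); pos_seq <- character(0); pos_lab <- character(0)
    for (f in seq_len(spec$num_families)) {
      motif <- .random_bases(spec$motif_length, rep(0.25, 4))
      for (i in seq_len(spec$family_size)) {
        len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
        m <- .mutate_motif(motif, spec$mutation_rate)
        offset <- sample.int(len - spec$motif_length + 1L, 1L) - 1L
        left <- if (offset > 0L) .random_bases(offset, comp) else ""
        right_len <- len - offset - spec$motif_length
        right <- if (right_len > 0L) .random_bases(right_len, comp) else ""
        pos_id <- c(pos_id, sprintf("fam%d_%04d", f, i))
        pos_seq <- c(pos_seq, paste0(left, m, right))
        pos_lab <- c(pos_lab, sprintf("fam%d", f))
      }
    }
    bg_len <- if (spec$background_size > 0L) {
      sample(spec$length_range[1L]:spec$length_range[2L],
             spec$background_size, replace = TRUE)
    } else integer(0)
    bg_seq <- vapply(bg_len, .random_bases, character(1), prob = comp)
    bg_id <- sprintf("bg_%05d", seq_len(spec$background_size))
  })
  positives <- seq_set(pos_id, pos_seq)
  background <- seq_set(bg_id, bg_seq)
  truth <- stats::setNames(c(pos_lab, rep("background", length(bg_id))),
                           c(pos_id, bg_id))
  list(positives = positives, background = background, truth = truth)
}
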