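# Internal helpers shared across modules: base encoding, gram indexing,
# and derived RNG seeds.

.BASES <- c("A", "C", "G", "T")

# byte -> 0..3 code table (NA for anything outside A/C/G/T)
.BASE_CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 0L
  x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L
  x[utf8ToInt("T")] <- 3L
  x
})

# Encode an A/C/G/T string as integer codes 0..3.
encode_seq <- function(s) {
  codes <- .BASE_CODE[utf8ToInt(s)]
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T}: ", s, call. = FALSE)
  }
  codes
}

decode_seq <- function(codes) {
  paste(.BASES[codes + 1L], collapse = "")
}

# 1-based base-4 indices of all overlapping w-grams in an encoded sequence.
# Index order is lexicographic with A < C < G < T.
gram_indices <- function(codes, w) {
  m <- length(codes) - w + 1L
  if (m < 1L) return(integer(0))
  idx <- codes[seq_len(m)]
  if (w > 1L) {
    for (j in 2:w) {
      idx <- idx * 4L + codes[j:(j + m - 1L)]
    }
  }
  idx + 1L
}

# All w-mers over {A,C,G,T} in lexicographic order (matches gram_indices).
all_grams <- function(w) {
  g <- ""
  for (j in seq_len(w)) {
    g <- as.vector(t(outer(g, .BASES, paste0)))
  }
  g
}

# Deterministically derive a child seed from a parent seed and a stream index,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 104729) %%
               2147483587) + 1L
}
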