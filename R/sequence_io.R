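# Sequence containers and FASTA / prediction-table I/O.
#
# All downstream stages assume an internal DNA alphabet {A,C,G,T}; RNA input
# (U) is mapped to T on read so that 4^k index arithmetic stays uniform.

#' Construct a sequence set
#'
#' A `seq_set` is the package's lightweight container for short nucleotide
#' sequences: parallel vectors of unique identifiers and uppercase A/C/G/T
#' strings, order preserved.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of sequences over \{A,C,G,T\} (same length as
#'   `id`).
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(id = character(0), seq = character(0)) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("id and seq must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop("sequences contain characters outside {A,C,G,T}: ",
         paste(utils::head(id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, seq = seq), class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
`[.seq_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], seq = x$seq[i]), class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<seq_set> %d sequence%s", n, if (n == 1L) "" else "s"))
  if (n > 0L) {
    cat(sprintf(", lengths %d-%d", min(nchar(x$seq)), max(nchar(x$seq))))
  }
  cat("\n")
  invisible(x)
}

#' @export
c.seq_set <- function(...) {
  parts <- list(...)
  seq_set(unlist(lapply(parts, `[[`, "id")),
          unlist(lapply(parts, `[[`, "seq")))
}

#' Sequence lengths and minimum length of a set
#'
#' @param x a `seq_set`.
#' @return `seq_lengths()`: integer vector of sequence lengths;
#'   `min_length()`: the smallest length in the set (errors on an empty set,
#'   where the minimum is undefined).
#' @export
seq_lengths <- function(x) nchar(x$seq)

#' @rdname seq_lengths
#' @export
min_length <- function(x) {
  if (length(x) == 0L) stop("min_length is undefined for an empty set",
                            call. = FALSE)
  min(nchar(x$seq))
}

#' Read nucleotide sequences from a FASTA file
#'
#' Records are uppercased and U is mapped to T, giving one canonical DNA
#' alphabet. The `alphabet_policy` controls what happens to residual
#' non-A/C/G/T characters:
#' \describe{
#'   \item{`"drop-ambiguous"`}{(default) records containing ambiguity codes or
#'     other symbols are removed, with a warning reporting how many.}
#'   \item{`"strict"`}{any character outside \{A,C,G,T,U\} is an error naming
#'     the offending record.}
#' }
#' Wrapped sequence lines are supported; the identifier is the header up to
#' the first whitespace (the remaining description is ignored for identity).
#'
#' @param path path to a FASTA file.
#' @param alphabet_policy `"drop-ambiguous"` or `"strict"`.
#' @return A [seq_set] in file order.
#' @export
read_fasta <- function(path, alphabet_policy = c("drop-ambiguous", "strict")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(seq_set())
  }
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- chartr("u", "t", chartr("U", "T", toupper(as.character(recs))))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (alphabet_policy == "strict") {
      stop("record '", ids[which(bad)[1L]],
           "' contains characters outside {A,C,G,T,U}", call. = FALSE)
    }
    warning(sum(bad), " record(s) with ambiguous characters dropped",
            call. = FALSE)
    ids <- ids[!bad]
    seqs <- seqs[!bad]
  }
  seq_set(ids, seqs)
}

#' Write a sequence set to FASTA
#'
#' @param x a `seq_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  dna <- Biostrings::DNAStringSet(x$seq)
  names(dna) <- x$id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write and read prediction tables
#'
#' Predictions are stored as a tab-separated table with a header row and
#' columns `id`, `label` (`piRNA` / `non-piRNA`) and `confidence` (printed
#' with six decimal digits), one row per sequence in input order.
#'
#' @param predictions data frame with columns `id`, `label`, `confidence`
#'   (confidences in \[0,1\]).
#' @param path output (or input) file path.
#' @return `write_predictions()`: `path`, invisibly. `read_predictions()`:
#'   the data frame.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("id", "label", "confidence") %in% names(predictions)))
  conf <- predictions$confidence
  ok <- is.na(conf) | (conf >= 0 & conf <= 1)
  if (!all(ok)) stop("confidences must lie in [0,1]", call. = FALSE)
  out <- data.frame(id = as.character(predictions$id),
                    label = as.character(predictions$label),
                    confidence = ifelse(is.na(conf), "NA",
                                        sprintf("%.6f", conf)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character", label = "character",
                                   confidence = "numeric"))
}
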