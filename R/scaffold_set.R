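#' Scaffold sets: named DNA sequences with an N-gap inventory
#'
#' A `ScaffoldSet` holds an ordered collection of uppercase DNA
#' sequences (alphabet A, C, G, T, N) together with the inventory of
#' their N-gaps. A gap is a maximal run of N; coordinates are 0-based
#' half-open throughout.
#'
#' @param seqs named character vector of DNA sequences. Names must be
#'   non-empty and unique. Lowercase input is upcased.
#' @return An object of class `ScaffoldSet` with elements `seqs` (named
#'   character vector) and `gaps` (data frame with columns `record_id`,
#'   `start`, `end`, `n_count`).
#' @export
#' @examples
#' s <- scaffold_set(c(s1 = "ACGTNNNACGT"))
#' s$gaps
scaffold_set <- function(seqs) {
  if (length(seqs) == 0) {
    return(structure(list(seqs = setNames(character(0), character(0)),
                          gaps = empty_gap_table()),
                     class = "ScaffoldSet"))
  }
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[[1]], call. = FALSE)
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[[1]]
    stop(sprintf("non-IUPAC character in '%s' at position %d",
                 ids[[i]], bad[[i]]), call. = FALSE)
  }
  if (any(nchar(seqs) < 1))
    stop("zero-length sequence: ", ids[which(nchar(seqs) < 1)[1]],
         call. = FALSE)
  structure(list(seqs = seqs, gaps = gap_inventory(seqs)),
            class = "ScaffoldSet")
}

empty_gap_table <- function() {
  data.frame(record_id = character(0), start = integer(0),
             end = integer(0), n_count = integer(0),
             stringsAsFactors = FALSE)
}

#' N-gap inventory of a set of sequences
#'
#' Finds every maximal run of N in each sequence.
#'
#' @param seqs named character vector of DNA sequences.
#' @return data frame with columns `record_id`, `start`, `end`
#'   (0-based half-open) and `n_count` (= end - start).
#' @export
gap_inventory <- function(seqs) {
  if (inherits(seqs, "ScaffoldSet")) seqs <- seqs$seqs
  hits <- gregexpr("N+", seqs)
  out <- lapply(seq_along(seqs), function(i) {
    m <- hits[[i]]
    if (m[[1]] == -1) return(NULL)
    st <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    data.frame(record_id = names(seqs)[[i]], start = st,
               end = st + len, n_count = len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_gap_table() else out
}

#' @export
print.ScaffoldSet <- function(x, ...) {
  cat(sprintf("ScaffoldSet: %d sequence(s), %s bp total, %d gap(s)\n",
              length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ","),
              nrow(x$gaps)))
  invisible(x)
}

#' @export
length.ScaffoldSet <- function(x) length(x$seqs)

#' Sequence lengths of a ScaffoldSet
#' @param set a `ScaffoldSet`.
#' @return named integer vector of sequence lengths.
#' @export
seq_lengths <- function(set) {
  stopifnot(inherits(set, "ScaffoldSet"))
  setNames(nchar(set$seqs), names(set$seqs))
}

#' Count of non-N bases per sequence
#' @param set a `ScaffoldSet`.
#' @return named integer vector of real (non-N) base counts.
#' @export
real_base_count <- function(set) {
  stopifnot(inherits(set, "ScaffoldSet"))
  n_per <- tapply(set$gaps$n_count, set$gaps$record_id, sum)
  lens <- seq_lengths(set)
  ns <- setNames(rep(0L, length(lens)), names(lens))
  ns[names(n_per)] <- as.integer(n_per)
  lens - ns
}

#' Read a FASTA file into a ScaffoldSet
#'
#' Uses Biostrings for parsing; sequences are upcased and the N-gap
#' inventory is recomputed on read. Duplicate ids and non-IUPAC
#' characters are errors.
#'
#' @param path FASTA file path.
#' @return a `ScaffoldSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- setNames(as.character(x), ids)
  scaffold_set(seqs)
}

#' Write a ScaffoldSet to FASTA
#'
#' @param set a `ScaffoldSet`.
#' @param path output path.
#' @param width line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path, width = 60L) {
  stopifnot(inherits(set, "ScaffoldSet"))
  x <- Biostrings::DNAStringSet(set$seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## substring in 0-based half-open coordinates
subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

n_run <- function(n) strrep("N", n)
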