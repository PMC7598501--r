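#' Read set container
#'
#' A `read_set` is a tibble with one row per sequencing read and at least
#' the columns `id` (unique identifier), `seq` (DNA string, may contain
#' N) and `qual` (Phred+33-encoded quality string of the same length).
#' Paired sets additionally carry `pair_id` and `mate` (1 or 2) columns;
#' both mates of a pair share `pair_id`.  Simulated read sets keep their
#' ground-truth origin in `chrom`, `start`, `end`, `strand`,
#' `origin_family` and `origin_subfamily` columns, which downstream
#' recovery tests use as an oracle.
#'
#' @param reads A data frame with at least `id` and `seq` columns.
#' @param default_phred Constant quality assigned when `qual` is absent.
#' @return A `read_set` tibble.
#' @export
read_set <- function(reads, default_phred = 30L) {
  reads <- as_tibble(reads)
  if (!all(c("id", "seq") %in% names(reads))) {
    stop("a read_set needs 'id' and 'seq' columns")
  }
  if (!"qual" %in% names(reads)) {
    reads$qual <- qual_string(nchar(reads$seq), default_phred)
  }
  validate_read_set(reads)
  class(reads) <- c("read_set", class(tibble()))
  reads
}

validate_read_set <- function(reads) {
  if (anyDuplicated(reads$id)) stop("read identifiers must be unique")
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("bases and qualities must have equal length per read")
  }
  if ("mate" %in% names(reads) && !all(reads$mate %in% c(1L, 2L))) {
    stop("mate must be 1 or 2")
  }
  invisible(reads)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s\n", nrow(x),
              if (is_paired(x)) sprintf(" (%d pairs)", nrow(x) / 2) else ""))
  NextMethod()
}

#' Number of reads in a read set
#' @param rs A [read_set()].
#' @return Integer count.
#' @export
n_reads <- function(rs) nrow(rs)

#' Is a read set paired?
#' @param rs A [read_set()].
#' @return Logical.
#' @export
is_paired <- function(rs) {
  all(c("pair_id", "mate") %in% names(rs)) && nrow(rs) > 0
}

#' Uniform read length of a set
#'
#' @param rs A [read_set()].
#' @return The common read length; errors if lengths differ.
#' @export
read_length <- function(rs) {
  if (nrow(rs) == 0) return(NA_integer_)
  len <- unique(nchar(rs$seq))
  if (length(len) != 1) stop("read set does not have uniform read length")
  len
}

# Subset while keeping the read_set class
subset_reads <- function(rs, idx) {
  out <- rs[idx, , drop = FALSE]
  class(out) <- class(rs)
  out
}
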