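#' Quality-filter a read set
#'
#' Retains exactly the reads in which the fraction of bases at or above
#' the Phred `cutoff` is at least `pass_fraction` (both boundaries
#' inclusive, so a 100-base read with 5 bases below cutoff passes at
#' pass_fraction 0.95).  Read order and content are preserved; only
#' membership changes.
#'
#' @param rs A [read_set()].
#' @param cutoff Phred quality cutoff (default 10).
#' @param pass_fraction Required fraction of passing bases (default
#'   0.95).
#' @return The filtered [read_set()].
#' @export
quality_filter <- function(rs, cutoff = 10L, pass_fraction = 0.95) {
  stopifnot(inherits(rs, "read_set"))
  if (pass_fraction < 0 || pass_fraction > 1) {
    stop("pass_fraction must be in [0, 1]")
  }
  if (nrow(rs) == 0) return(rs)
  q <- qual_ints(rs$qual)
  frac <- vapply(q, function(v) mean(v >= cutoff), numeric(1))
  subset_reads(rs, frac >= pass_fraction)
}

#' Trim reads to a uniform length
#'
#' Reads longer than `target` are truncated from the 3' end; reads
#' shorter than `target` are dropped, so every retained read has exactly
#' `target` bases.
#'
#' @param rs A [read_set()].
#' @param target Target read length in nt (default 151).
#' @return The trimmed [read_set()].
#' @export
trim_to_length <- function(rs, target = 151L) {
  stopifnot(inherits(rs, "read_set"), target >= 1)
  if (nrow(rs) == 0) return(rs)
  len <- nchar(rs$seq)
  out <- subset_reads(rs, len >= target)
  out$seq <- substr(out$seq, 1L, target)
  out$qual <- substr(out$qual, 1L, target)
  out
}

#' Interlace read pairs
#'
#' Orders a paired read set as mate1, mate2, mate1, mate2, ... .  Pairs
#' that lost a mate in upstream filtering are dropped entirely
#' (clustering operates on interlaced intact pairs, so orphans are not
#' kept).
#'
#' @param rs A paired [read_set()].
#' @return An interlaced [read_set()].
#' @export
interlace_pairs <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (nrow(rs) == 0) {
    if (!all(c("pair_id", "mate") %in% names(rs))) {
      stop("invalid input: read set is not paired")
    }
    return(rs)
  }
  if (!is_paired(rs)) stop("invalid input: read set is not paired")
  counts <- table(rs$pair_id)
  intact <- names(counts)[counts == 2]
  out <- subset_reads(rs, rs$pair_id %in% intact)
  subset_reads(out, order(out$pair_id, out$mate))
}

#' Randomly subsample a read set to a target coverage
#'
#' Uniform sampling without replacement of
#' [reads_for_coverage()]`(genome_length, target_coverage, read_length)`
#' reads.  Paired sets are sampled by pair so mates stay together.  A
#' warning is emitted when the target coverage is outside the 0.01-0.50x
#' band recommended for repeat discovery by read clustering.
#'
#' @param rs A non-empty [read_set()].
#' @param genome_length Genome length in bp.
#' @param target_coverage Target coverage (> 0).
#' @param read_length Read length in nt.
#' @param seed Integer seed; the sample is reproducible from it.
#' @return The subsampled [read_set()] (original order preserved).
#' @export
subsample_to_coverage <- function(rs, genome_length, target_coverage,
                                  read_length = 151L, seed = 1L) {
  stopifnot(inherits(rs, "read_set"))
  if (target_coverage <= 0) stop("target_coverage must be > 0")
  if (nrow(rs) == 0) stop("insufficient reads: read set is empty")
  if (target_coverage < 0.01 || target_coverage > 0.50) {
    warning("target coverage ", target_coverage,
            "x is outside the recommended 0.01-0.50x range")
  }
  paired <- is_paired(rs)
  n <- reads_for_coverage(genome_length, target_coverage, read_length,
                          paired)
  if (n > nrow(rs)) {
    stop(sprintf("insufficient reads: need %d, have %d", n, nrow(rs)))
  }
  withr_seed(seed, {
    if (paired) {
      ids <- unique(rs$pair_id)
      keep <- sample(ids, n %/% 2L)
      subset_reads(rs, rs$pair_id %in% keep)
    } else {
      keep <- sort(sample.int(nrow(rs), n))
      subset_reads(rs, keep)
    }
  })
}
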