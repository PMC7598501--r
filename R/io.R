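#' Read and write FASTQ read sets
#'
#' FASTQ I/O (Phred+33) for [read_set()]s.  Writing then reading a set
#' round-trips identifiers, bases and qualities losslessly (ground-truth
#' origin columns live only in memory).  Paired sets can be written
#' interleaved (single file) or as two mate files with the standard
#' `_1`/`_2` suffixes.
#'
#' @param rs A [read_set()].
#' @param path Output file path (for `interleaved = FALSE` the mate
#'   suffix is inserted before the extension).
#' @param interleaved Write mates alternately to a single file?
#' @return `write_fastq` returns the written path(s) invisibly;
#'   `read_fastq` returns a [read_set()].
#' @export
write_fastq <- function(rs, path, interleaved = TRUE) {
  stopifnot(inherits(rs, "read_set"))
  if (!interleaved && is_paired(rs)) {
    paths <- vapply(c(1L, 2L), function(m) {
      sub("(\\.[^.]+)$", sprintf("_%d\\1", m), path)
    }, character(1))
    write_fastq_file(subset_reads(rs, rs$mate == 1L), paths[1])
    write_fastq_file(subset_reads(rs, rs$mate == 2L), paths[2])
    return(invisible(paths))
  }
  write_fastq_file(rs, path)
  invisible(path)
}

write_fastq_file <- function(rs, path) {
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- rs$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(rs$qual))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # parsing drops the quality metadata columns during coercion by
  # design; the qualities are read back explicitly, so muffle that one
  # warning
  withCallingHandlers({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    read_set(tibble(id = names(x), seq = unname(as.character(x)),
                    qual = unname(as.character(Biostrings::quality(x)))))
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Read and write FASTA sequence sets
#'
#' @param seqs Named character vector or
#'   [Biostrings::DNAStringSet].
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read and write BED interval annotations
#'
#' On-disk intervals use the BED convention (0-based, half-open); in
#' memory the package uses 1-based inclusive coordinates, so a BED line
#' `chr1 0 360` round-trips to `start = 1, end = 360` (length 360).
#' Repeat annotations encode family and subfamily in the name column as
#' `family|subfamily`.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and either a
#'   `name` column or `family`/`subfamily` columns.
#' @param path File path.
#' @return `read_bed` returns a tibble with 1-based inclusive
#'   coordinates and a `name` column (split into `family`/`subfamily`
#'   when the names carry them).
#' @export
write_bed <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) {
    intervals$name
  } else if (all(c("family", "subfamily") %in% names(intervals))) {
    sprintf("%s|%d", intervals$family, intervals$subfamily)
  } else {
    rep(".", nrow(intervals))
  }
  df <- data.frame(chrom = intervals$chrom,
                   start = intervals$start - 1L,
                   end = intervals$end, name = name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed BED: fewer than 3 columns")
  out <- tibble(chrom = as.character(df[[1]]),
                start = as.integer(df[[2]]) + 1L,
                end = as.integer(df[[3]]),
                name = if (ncol(df) >= 4) as.character(df[[4]]) else ".")
  if (all(grepl("^[^|]+\\|\\d+$", out$name))) {
    parts <- strsplit(out$name, "|", fixed = TRUE)
    out$family <- vapply(parts, `[[`, character(1), 1)
    out$subfamily <- as.integer(vapply(parts, `[[`, character(1), 2))
  }
  out
}

#' Read and write intensity profiles as TSV
#'
#' Tab-separated files with a header row: a `position` column followed
#' by one column per channel.
#'
#' @param p An [intensity_profile()].
#' @param path File path.
#' @return `read_profile_tsv` returns an [intensity_profile()].
#' @export
write_profile_tsv <- function(p, path) {
  write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"position" %in% names(df)) {
    stop("malformed profile TSV: no 'position' column")
  }
  intensity_profile(df$position, df[setdiff(names(df), "position")])
}

#' Write a cluster summary table
#'
#' TSV with one row per cluster: id, size, genome proportion and
#' annotation (when present).
#'
#' @param clusters Cluster tibble from [cluster_reads()].
#' @param path File path.
#' @export
write_cluster_summary <- function(clusters, path) {
  df <- clusters[setdiff(names(clusters), "members")]
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
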