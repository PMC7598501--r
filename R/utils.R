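#' Random DNA sequence
#'
#' Draws an i.i.d. uniform sequence over A, C, G, T.  Used for background
#' genome sequence and for repeat-family ancestor consensuses.
#'
#' @param n Sequence length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of character sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a per-stage seed from a global seed
#'
#' Pipeline stages draw their randomness from seeds derived
#' deterministically from one global seed, so that any stage can be
#' re-run in isolation and reproduce its output.  The scheme is
#' `seed * 64 + stage index` (mod 2^31 - 1), with stage indices fixed by
#' [pipeline_stages()].
#'
#' @param seed Global integer seed.
#' @param stage Stage name, one of [pipeline_stages()].
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- pipeline_stages()
  idx <- match(stage, stages)
  if (is.na(idx)) stop("unknown pipeline stage: ", stage)
  as.integer((as.numeric(seed) * 64 + idx) %% (2^31 - 1))
}

#' Pipeline stage names, in execution order
#' @return Character vector of stage names.
#' @export
pipeline_stages <- function() {
  c("genome", "wgs", "chip", "preprocess", "subsample", "cluster",
    "map_chip", "map_input", "profiles", "cpm")
}

#' Inclusive span of a 1-based genomic interval
#'
#' Length in bp of a locus printed in 1-based inclusive coordinates,
#' e.g. a gene annotated at positions 11651877-11652254 spans 378 bp.
#'
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @return Integer span in bp.
#' @export
interval_span <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  as.integer(end - start + 1)
}

#' Protein length encoded by an intron-less coding sequence
#'
#' Number of amino-acid residues encoded by a CDS of `nt` bases,
#' counting the stop codon as non-coding (nt/3 - 1).
#'
#' @param nt CDS length in bp; must be a multiple of 3.
#' @return Integer residue count.
#' @export
protein_length <- function(nt) {
  if (any(nt %% 3 != 0)) stop("coding length must be a multiple of 3")
  as.integer(nt / 3 - 1)
}

#' Round half away from zero
#'
#' Reporting-style rounding (5 rounds up), unlike R's banker rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Constant-quality string (Phred+33)
qual_string <- function(len, phred = 30L) {
  vapply(len, function(l) strrep(intToUtf8(phred + 33L), l), character(1))
}

# Phred integer vectors from a quality string
qual_ints <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}
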