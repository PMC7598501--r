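# Fixtures are built in code at test time; nothing is stored on disk.

# n reads sampled from a tandem array of `monomer`, random phase and
# strand, with optional per-read substitution rate
sample_array_reads <- function(monomer, n, read_len = 151L, sub_rate = 0,
                               seed = 1L, prefix = "sat") {
  set.seed(seed)
  copies <- ceiling((read_len * 3) / nchar(monomer)) + 2L
  array <- strrep(monomer, copies)
  starts <- sample.int(nchar(array) - read_len + 1L, n, replace = TRUE)
  seqs <- substring(array, starts, starts + read_len - 1L)
  if (sub_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      v <- strsplit(s, "")[[1]]
      hit <- runif(length(v)) < sub_rate
      v[hit] <- vapply(v[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  minus <- runif(n) < 0.5
  seqs[minus] <- revcomp(seqs[minus])
  read_set(tibble::tibble(id = sprintf("%s%04d", prefix, seq_len(n)),
                          seq = seqs))
}

# n random background reads
background_reads <- function(n, read_len = 151L, seed = 1L,
                             prefix = "bg") {
  set.seed(seed)
  read_set(tibble::tibble(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    seq = replicate(n, random_dna(read_len))))
}

rbind_read_sets <- function(...) {
  read_set(do.call(rbind, lapply(list(...), tibble::as_tibble)))
}

# Independent brute-force similarity-graph oracle built on
# Biostrings::pairwiseAlignment with the same scoring objective
# (match +1, mismatch -2, linear gap -3).  Orientation is chosen by
# score (ties to forward), then both thresholds are checked on that
# orientation's alignment, mirroring the edge contract.
brute_force_edges <- function(rs, min_identity = 0.90, min_overlap = 0.55) {
  n <- nrow(rs)
  len <- read_length(rs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  seqs <- Biostrings::DNAStringSet(rs$seq)
  rcs <- Biostrings::reverseComplement(seqs)
  out <- list()
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    fw <- Biostrings::pairwiseAlignment(seqs[idx], seqs[[i]],
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 3)
    rv <- Biostrings::pairwiseAlignment(rcs[idx], seqs[[i]],
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 3)
    use_rv <- Biostrings::score(rv) > Biostrings::score(fw)
    aln_cols <- function(pa) {
      nchar(as.character(Biostrings::alignedPattern(pa)))
    }
    cols <- ifelse(use_rv, aln_cols(rv), aln_cols(fw))
    matches <- ifelse(use_rv, Biostrings::nmatch(rv),
                      Biostrings::nmatch(fw))
    ident <- ifelse(cols > 0, matches / cols, 0)
    keep <- ident >= min_identity & pmin(1, cols / len) >= min_overlap
    if (any(keep)) {
      out[[length(out) + 1]] <- data.frame(read_a = rs$id[i],
                                           read_b = rs$id[idx[keep]])
    }
  }
  if (length(out) == 0) {
    return(data.frame(read_a = character(), read_b = character()))
  }
  do.call(rbind, out)
}

# canonical unordered pair keys for edge-set comparison
edge_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges$read_a, edges$read_b),
             pmax(edges$read_a, edges$read_b)))
}

# membership partition (sorted member lists) for cluster comparison
cluster_partition <- function(clusters) {
  parts <- lapply(clusters$members, sort)
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# small three-family genome for clustering recovery tests
small_test_genome <- function(seed = 1L, genome_length = 6e5L) {
  fams <- list(
    repeat_family_spec("satA", 360L, 0.12, n_subfamilies = 1L,
                       organization = "tandem", centromeric = TRUE),
    repeat_family_spec("satB", 180L, 0.06, n_subfamilies = 1L,
                       organization = "tandem", centromeric = FALSE),
    repeat_family_spec("mobC", 900L, 0.03, n_subfamilies = 1L,
                       organization = "dispersed", centromeric = FALSE))
  build_genome(genome_spec(genome_length, fams, n_chromosomes = 1L,
                           seed = seed))
}
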