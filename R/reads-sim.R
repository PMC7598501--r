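#' Number of reads needed for a target coverage
#'
#' `ceiling(coverage * genome_length / read_length)`, rounded up to the
#' nearest even integer for paired sets so that pairs stay whole.  For a
#' 204-Mb genome at 0.2x with 151-nt paired reads this gives 270,200
#' reads.
#'
#' @param genome_length Genome length in bp.
#' @param coverage Target coverage (>= 0).
#' @param read_length Read length in nt.
#' @param paired Round up to an even read count?
#' @return Integer read count.
#' @export
reads_for_coverage <- function(genome_length, coverage, read_length,
                               paired = TRUE) {
  if (coverage < 0) stop("coverage must be >= 0")
  n <- ceiling(coverage * genome_length / read_length)
  if (paired && n %% 2 == 1) n <- n + 1
  as.integer(n)
}

#' Simulate whole-genome shotgun reads
#'
#' Read (or fragment) start positions are uniform over the genome, both
#' strands are sampled with probability 0.5, and every read records its
#' true source interval and originating repeat family for use as a
#' ground-truth oracle.  Qualities are constant Phred 30 by default
#' (Phred+33 encoding).
#'
#' @param genome An `annotated_genome` from [build_genome()].
#' @param coverage Target coverage; the read count follows
#'   [reads_for_coverage()].
#' @param read_length Read length in nt (default 151).
#' @param paired Simulate read pairs from fragments?
#' @param seed Integer seed.
#' @param fragment_length Fragment length for paired reads.
#' @param phred Constant per-base quality.
#' @param error_rate Optional uniform substitution rate (default 0).
#' @return A [read_set()].
#' @export
simulate_wgs_reads <- function(genome, coverage, read_length = 151L,
                               paired = TRUE, seed = 1L,
                               fragment_length = 350L, phred = 30L,
                               error_rate = 0) {
  stopifnot(inherits(genome, "annotated_genome"))
  L <- genome_length(genome)
  wl <- Biostrings::width(genome$sequences)
  if (read_length > min(wl)) {
    stop("read_length exceeds the shortest chromosome")
  }
  n <- reads_for_coverage(L, coverage, read_length, paired)
  if (n == 0) return(empty_read_set())
  withr_seed(seed, {
    if (paired) {
      frag <- min(fragment_length, min(wl))
      np <- n %/% 2L
      ci <- sample.int(length(wl), np, replace = TRUE, prob = wl)
      fstart <- floor(runif(np) * (wl[ci] - frag + 1)) + 1L
      minus <- runif(np) < 0.5
      m1s <- ifelse(minus, fstart + frag - read_length, fstart)
      m2s <- ifelse(minus, fstart, fstart + frag - read_length)
      idx <- rep(seq_len(np), each = 2)
      mate <- rep(c(1L, 2L), np)
      start <- as.integer(ifelse(mate == 1, m1s[idx], m2s[idx]))
      strand <- ifelse(mate == 1, ifelse(minus[idx], "-", "+"),
                       ifelse(minus[idx], "+", "-"))
      chrom <- names(genome$sequences)[ci[idx]]
      pair_id <- sprintf("wgs%07d", idx)
      id <- paste0(pair_id, "/", mate)
      rs <- extract_reads(genome, chrom, start, read_length, strand,
                          id, phred, error_rate)
      rs$pair_id <- pair_id
      rs$mate <- mate
    } else {
      ci <- sample.int(length(wl), n, replace = TRUE, prob = wl)
      start <- floor(runif(n) * (wl[ci] - read_length + 1)) + 1L
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      chrom <- names(genome$sequences)[ci]
      id <- sprintf("wgs%07d", seq_len(n))
      rs <- extract_reads(genome, chrom, as.integer(start), read_length,
                          strand, id, phred, error_rate)
    }
    read_set(rs)
  })
}

#' Chromatin occupancy model for ChIP simulation
#'
#' CenH3 pull-down is modeled as position-weighted sampling: reads
#' starting inside an *occupied* centromeric array of a weighted family
#' are drawn with that family's weight, all other positions with
#' `background_weight`.  Only `occupied_fraction` of a family's
#' centromeric arrays are occupied, reflecting partial CenH3 occupancy
#' of abundant repeats.
#'
#' @param weights Named numeric vector of per-family sampling weights
#'   (relative pull-down probability), all >= 0.
#' @param background_weight Weight of all unoccupied positions (>= 0).
#' @param occupied_fraction Fraction of each weighted family's
#'   centromeric arrays that are occupied, in (0, 1].
#' @return An `occupancy_model` object.
#' @export
occupancy_model <- function(weights, background_weight = 1,
                            occupied_fraction = 1) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0) || background_weight < 0) {
    stop("weights must be >= 0")
  }
  if (all(weights == 0) && background_weight == 0) {
    stop("degenerate model: all weights are zero")
  }
  if (occupied_fraction <= 0 || occupied_fraction > 1) {
    stop("occupied_fraction must be in (0, 1]")
  }
  structure(list(weights = weights, background_weight = background_weight,
                 occupied_fraction = occupied_fraction),
            class = "occupancy_model")
}

#' Simulate a ChIP / input read-set pair
#'
#' Input reads are sampled uniformly over the genome; ChIP reads are
#' sampled with probability proportional to the position weights of the
#' [occupancy_model()].  Both sets have exactly `n_reads` single-end
#' reads and keep their ground-truth origin columns.
#'
#' @param genome An `annotated_genome`.
#' @param model An [occupancy_model()].
#' @param n_reads Reads per library (>= 0).
#' @param read_length Read length in nt.
#' @param seed Integer seed.
#' @param phred Constant per-base quality.
#' @return List with elements `chip` and `input`, both [read_set()]s.
#' @export
simulate_chip_input <- function(genome, model, n_reads, read_length = 151L,
                                seed = 1L, phred = 30L) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(model, "occupancy_model"))
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (n_reads == 0) {
    return(list(chip = empty_read_set(), input = empty_read_set()))
  }
  withr_seed(seed, {
    wt <- chip_weight_table(genome, model)
    chip <- sample_weighted_reads(genome, wt, n_reads, read_length,
                                  prefix = "chip", phred = phred)
    uni <- wt
    uni$weight <- 1
    input <- sample_weighted_reads(genome, uni, n_reads, read_length,
                                   prefix = "input", phred = phred)
    list(chip = chip, input = input)
  })
}

#' Per-interval ChIP sampling weights implied by an occupancy model
#'
#' Partitions the genome into intervals with a constant read-start
#' sampling weight: occupied centromeric arrays of weighted families get
#' the family weight, everything else the background weight.  Which
#' arrays are occupied is drawn from the current RNG state, so call this
#' within a seeded context for reproducibility.  Exposed mainly so that
#' expected per-family enrichment can be computed in closed form.
#'
#' @param genome An `annotated_genome`.
#' @param model An [occupancy_model()].
#' @return Tibble with `chrom`, `start`, `end`, `weight`, `family`,
#'   `subfamily` (family columns are NA for background intervals).
#' @export
chip_weight_table <- function(genome, model) {
  ann <- genome$annotations
  occ <- ann[0, ]
  for (fam in names(model$weights)) {
    if (model$weights[[fam]] == 0) next
    rows <- ann[ann$family == fam & in_centromere(ann, genome$centromeres), ]
    if (nrow(rows) == 0) next
    k <- max(1L, round(model$occupied_fraction * nrow(rows)))
    occ <- rbind(occ, cbind(rows[sample.int(nrow(rows), k), ],
                            weight = model$weights[[fam]]))
  }
  wl <- Biostrings::width(genome$sequences)
  bg <- list()
  for (ci in seq_along(wl)) {
    ch <- names(genome$sequences)[ci]
    rows <- occ[occ$chrom == ch, ]
    rows <- rows[order(rows$start), ]
    bounds <- c(0L, rbind(rows$start - 1L, rows$end), wl[ci])
    starts <- bounds[seq(1, length(bounds), by = 2)] + 1L
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends >= starts
    bg[[ci]] <- tibble(chrom = ch, start = starts[keep], end = ends[keep],
                       weight = 1 * 0 + model$background_weight,
                       family = NA_character_, subfamily = NA_integer_)
  }
  out <- rbind(
    tibble(chrom = occ$chrom, start = occ$start, end = occ$end,
           weight = occ$weight, family = occ$family,
           subfamily = occ$subfamily),
    do.call(rbind, bg))
  out[order(out$chrom, out$start), ]
}

# TRUE for annotation rows fully inside a centromere interval
in_centromere <- function(ann, centromeres) {
  if (nrow(ann) == 0) return(logical(0))
  vapply(seq_len(nrow(ann)), function(i) {
    ce <- centromeres[centromeres$chrom == ann$chrom[i], ]
    any(ann$start[i] >= ce$start & ann$end[i] <= ce$end)
  }, logical(1))
}

# sample n single-end reads with start probability proportional to
# interval weight
sample_weighted_reads <- function(genome, wt, n, read_length, prefix,
                                  phred) {
  mass <- wt$weight * (wt$end - wt$start + 1)
  if (sum(mass) <= 0) stop("degenerate model: total sampling mass is zero")
  ri <- sample.int(nrow(wt), n, replace = TRUE, prob = mass)
  pos <- wt$start[ri] +
    floor(runif(n) * (wt$end[ri] - wt$start[ri] + 1))
  wl <- setNames(Biostrings::width(genome$sequences),
                 names(genome$sequences))
  maxs <- wl[wt$chrom[ri]] - read_length + 1L
  start <- as.integer(pmin(pos, maxs))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  id <- sprintf("%s%07d", prefix, seq_len(n))
  read_set(extract_reads(genome, wt$chrom[ri], start, read_length, strand,
                         id, phred, error_rate = 0))
}

# extract read sequences and ground-truth origin columns
extract_reads <- function(genome, chrom, start, read_length, strand, id,
                          phred, error_rate) {
  end <- start + read_length - 1L
  seqs <- as.character(Biostrings::subseq(
    genome$sequences[chrom], start = start, end = end))
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  if (error_rate > 0) seqs <- add_substitutions(seqs, error_rate)
  fam <- origin_family(genome, chrom, start, end)
  tibble(id = id, seq = unname(seqs),
         qual = qual_string(rep(read_length, length(seqs)), phred),
         chrom = chrom, start = start, end = end, strand = strand,
         origin_family = fam$family, origin_subfamily = fam$subfamily)
}

# majority-overlap family annotation of read source intervals
origin_family <- function(genome, chrom, start, end) {
  n <- length(chrom)
  fam <- rep(NA_character_, n)
  sub <- rep(NA_integer_, n)
  ann <- genome$annotations
  if (nrow(ann) > 0) {
    q <- IRanges::IRanges(start, end)
    s <- IRanges::IRanges(ann$start, ann$end)
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same <- chrom[qh] == ann$chrom[sh]
    qh <- qh[same]; sh <- sh[same]
    if (length(qh) > 0) {
      ov <- pmin(end[qh], ann$end[sh]) - pmax(start[qh], ann$start[sh]) + 1
      keep <- ov > (end[qh] - start[qh] + 1) / 2
      qh <- qh[keep]; sh <- sh[keep]
      fam[qh] <- ann$family[sh]
      sub[qh] <- ann$subfamily[sh]
    }
  }
  list(family = fam, subfamily = sub)
}

add_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

empty_read_set <- function() {
  read_set(tibble(id = character(), seq = character(), qual = character()))
}

#' Expected per-family ChIP/input origin-read ratio
#'
#' Closed-form expectation of the ratio of ChIP to input read origins
#' for each family, computed from the interval weight table: for family
#' f with start-position mass m_f out of total mass M under the model,
#' and base fraction b_f under uniform sampling, the expected ratio is
#' (m_f / M) / b_f.
#'
#' @param genome An `annotated_genome`.
#' @param weight_table Output of [chip_weight_table()] (pass the same
#'   table used for sampling to condition on the realized occupancy).
#' @return Named numeric vector of expected ratios per family.
#' @export
expected_family_enrichment <- function(genome, weight_table) {
  wt <- weight_table
  len <- wt$end - wt$start + 1
  mass <- wt$weight * len
  M <- sum(mass)
  L <- sum(len)
  fams <- unique(genome$annotations$family)
  # weight table splits by occupancy, not family; recover family masses
  # by intersecting annotation rows with weight intervals
  out <- vapply(fams, function(fam) {
    rows <- genome$annotations[genome$annotations$family == fam, ]
    fmass <- 0; fbase <- 0
    for (i in seq_len(nrow(rows))) {
      sel <- wt$chrom == rows$chrom[i] & wt$start <= rows$end[i] &
        wt$end >= rows$start[i]
      w <- wt[sel, ]
      ov <- pmin(w$end, rows$end[i]) - pmax(w$start, rows$start[i]) + 1
      fmass <- fmass + sum(w$weight * ov)
      fbase <- fbase + sum(ov)
    }
    (fmass / M) / (fbase / L)
  }, numeric(1))
  setNames(out, fams)
}
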