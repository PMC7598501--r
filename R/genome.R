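#' Specify a synthetic genome
#'
#' The genome is a set of monocentric chromosomes, each with one
#' centromere interval covering `centromere_fraction` of its length.
#' Tandem repeat families marked `centromeric` are planted inside the
#' centromere intervals (with 20% of their arrays spilling over into the
#' flanking pericentromere); other tandem families and dispersed
#' families are planted in the chromosome arms; the remaining sequence
#' is i.i.d. random background.
#'
#' @param genome_length Total genome length in bp.
#' @param families List of [repeat_family_spec()] objects.
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param centromere_fraction Relative centromere extent per chromosome,
#'   in (0, 1).  The default 0.435 matches the cytological average
#'   measured for extended beetle metapolycentromeres.
#' @param seed Integer seed; the genome is reproducible from the spec.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(genome_length, families = tribolium_like_families(),
                        n_chromosomes = 2L, centromere_fraction = 0.435,
                        seed = 1L) {
  genome_length <- as.integer(genome_length)
  n_chromosomes <- as.integer(n_chromosomes)
  stopifnot(genome_length >= 1L, n_chromosomes >= 1L)
  if (centromere_fraction <= 0 || centromere_fraction >= 1) {
    stop("centromere_fraction must be in (0, 1)")
  }
  if (length(families) > 0) {
    stopifnot(all(vapply(families, inherits, logical(1), "repeat_family_spec")))
    total <- sum(vapply(families, `[[`, numeric(1), "genome_fraction"))
    if (total > 1) stop("infeasible spec: family genome fractions sum to > 1")
    nm <- vapply(families, `[[`, character(1), "name")
    if (anyDuplicated(nm)) stop("family names must be unique")
    names(families) <- nm
  }
  structure(
    list(genome_length = genome_length, families = families,
         n_chromosomes = n_chromosomes,
         centromere_fraction = centromere_fraction, seed = as.integer(seed)),
    class = "genome_spec")
}

#' Repeat families emulating the red flour beetle repeatome
#'
#' The default family set mirrors the published repeat landscape of
#' *Tribolium castaneum*: a 360-bp-monomer major satellite in five
#' subfamilies diverged up to 30% making up 17% of the genome and
#' concentrated at (peri)centromeres; a ~180-bp euchromatic minor
#' satellite at 0.5%; a novel 73-bp centromeric satellite at 0.05%; a
#' 192-bp 5S rDNA unit composed of a 119-bp gene plus a 73-bp
#' non-transcribed spacer; dispersed retroelement-like repeats; and
#' short interstitial (TCAGG)n-like arrays of 100-400 bp.
#'
#' @param major_fraction Genome fraction of the major satellite.
#' @param rdna_gene_bp,rdna_spacer_bp 5S rRNA gene and spacer lengths;
#'   their sum is the tandem unit length (default 119 + 73 = 192 bp).
#' @return Named list of [repeat_family_spec()] objects.
#' @export
tribolium_like_families <- function(major_fraction = 0.17,
                                    rdna_gene_bp = 119L,
                                    rdna_spacer_bp = 73L) {
  list(
    repeat_family_spec("major_sat", 360L, major_fraction,
                       n_subfamilies = 5L, max_subfamily_divergence = 0.30,
                       organization = "tandem", centromeric = TRUE),
    repeat_family_spec("minor_sat180", 180L, 0.005, n_subfamilies = 2L,
                       max_subfamily_divergence = 0.10,
                       organization = "tandem", centromeric = FALSE),
    repeat_family_spec("minor_sat73", 73L, 0.0005,
                       organization = "tandem", centromeric = TRUE,
                       array_bp = 1500),
    repeat_family_spec("rdna_5s", rdna_gene_bp + rdna_spacer_bp, 0.002,
                       organization = "tandem", centromeric = FALSE),
    repeat_family_spec("retroelement", 1200L, 0.05,
                       organization = "dispersed", centromeric = FALSE),
    repeat_family_spec("its_tcagg", 5L, 0.001,
                       organization = "tandem", centromeric = FALSE,
                       array_bp = 250)
  ) -> fams
  names(fams) <- vapply(fams, `[[`, character(1), "name")
  fams
}

#' Build an annotated synthetic genome
#'
#' Plants every family of the spec as described in [genome_spec()] and
#' records ground-truth annotations for each planted copy.  Tandem
#' arrays are head-to-tail monomer runs of a single subfamily consensus;
#' dispersed copies are isolated monomers.  Annotation intervals are
#' 1-based inclusive, never overlap and never cross chromosome ends.
#'
#' @param spec A [genome_spec()].
#' @return An `annotated_genome`: list with `sequences` (a
#'   [Biostrings::DNAStringSet]), `annotations` and `centromeres`
#'   tibbles, the subfamily `library` and the `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr_seed(spec$seed, build_genome_impl(spec))
}

build_genome_impl <- function(spec) {
  L <- spec$genome_length
  nc <- spec$n_chromosomes
  chrom_len <- rep(L %/% nc, nc)
  chrom_len[seq_len(L %% nc)] <- chrom_len[seq_len(L %% nc)] + 1L
  chroms <- paste0("chr", seq_len(nc))

  library <- lapply(seq_along(spec$families), function(i) {
    build_family_library(spec$families[[i]], seed = spec$seed + i)
  })
  names(library) <- names(spec$families)

  seqs <- character(nc)
  ann <- list()
  cens <- list()

  # per-family copy budgets per chromosome (largest remainder)
  budgets <- lapply(spec$families, function(f) {
    total <- round(f$genome_fraction * L / f$monomer_length)
    split_largest_remainder(total, chrom_len / sum(chrom_len))
  })

  for (ci in seq_len(nc)) {
    clen <- chrom_len[ci]
    cen_len <- round(spec$centromere_fraction * clen)

    cen_blocks <- list(); peri_blocks <- list(); arm_blocks <- list()
    for (fi in seq_along(spec$families)) {
      f <- spec$families[[fi]]
      copies <- budgets[[fi]][ci]
      if (copies < 1) next
      lib <- library[[fi]]
      if (f$organization == "dispersed") {
        arm_blocks <- c(arm_blocks, monomer_blocks(f, lib, copies))
      } else if (f$centromeric) {
        arrays <- make_arrays(f, lib, copies)
        spill <- spill_over_arrays(arrays)
        cen_blocks <- c(cen_blocks, arrays[!spill])
        peri_blocks <- c(peri_blocks, arrays[spill])
      } else {
        arm_blocks <- c(arm_blocks, make_arrays(f, lib, copies))
      }
    }

    cen_bp <- sum(vapply(cen_blocks, `[[`, integer(1), "len"))
    if (cen_bp > cen_len) {
      stop("infeasible spec: centromeric arrays exceed the centromere ",
           "interval on ", chroms[ci])
    }
    peri_bp <- vapply(peri_blocks, `[[`, integer(1), "len")
    # alternate pericentromeric arrays between the two centromere flanks
    left_peri <- peri_blocks[seq_along(peri_blocks) %% 2 == 1]
    right_peri <- peri_blocks[seq_along(peri_blocks) %% 2 == 0]
    arm_bp_total <- clen - cen_len - sum(peri_bp)
    if (arm_bp_total < sum(vapply(arm_blocks, `[[`, integer(1), "len"))) {
      stop("infeasible spec: arm repeats exceed available arm length on ",
           chroms[ci])
    }
    left_len <- arm_bp_total %/% 2
    right_len <- arm_bp_total - left_len
    # distribute arm blocks between the two arms at random
    if (length(arm_blocks) > 0) {
      side <- sample(c(TRUE, FALSE), length(arm_blocks), replace = TRUE)
      repeat {
        lb <- sum(vapply(arm_blocks[side], `[[`, integer(1), "len"))
        rb <- sum(vapply(arm_blocks[!side], `[[`, integer(1), "len"))
        if (lb <= left_len && rb <= right_len) break
        side <- if (lb > left_len) {
          replace(side, sample(which(side), 1), FALSE)
        } else {
          replace(side, sample(which(!side), 1), TRUE)
        }
      }
      left_arm <- layout_region(arm_blocks[side], left_len)
      right_arm <- layout_region(arm_blocks[!side], right_len)
    } else {
      left_arm <- layout_region(list(), left_len)
      right_arm <- layout_region(list(), right_len)
    }
    cen_region <- layout_region(cen_blocks, cen_len)
    left_peri_region <- layout_region(left_peri, sum(vapply(
      left_peri, `[[`, integer(1), "len")), shuffle = FALSE)
    right_peri_region <- layout_region(right_peri, sum(vapply(
      right_peri, `[[`, integer(1), "len")), shuffle = FALSE)

    segments <- list(left_arm, left_peri_region, cen_region,
                     right_peri_region, right_arm)
    offsets <- cumsum(c(0, vapply(segments, `[[`, numeric(1), "len")))
    seqs[ci] <- paste(vapply(segments, `[[`, character(1), "seq"),
                      collapse = "")
    seg_ann <- do.call(rbind, lapply(seq_along(segments), function(si) {
      a <- segments[[si]]$ann
      if (nrow(a) == 0) return(a)
      a$start <- a$start + offsets[si]
      a$end <- a$end + offsets[si]
      a
    }))
    seg_ann$chrom <- rep(chroms[ci], nrow(seg_ann))
    ann[[ci]] <- seg_ann
    cen_start <- offsets[3] + 1L
    cens[[ci]] <- tibble(chrom = chroms[ci], start = cen_start,
                         end = offsets[3] + cen_len)
  }

  annotations <- do.call(rbind, ann)
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- tibble(chrom = character(), start = integer(),
                          end = integer(), family = character(),
                          subfamily = integer())
  } else {
    annotations <- as_tibble(annotations[, c("chrom", "start", "end",
                                             "family", "subfamily")])
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- chroms
  structure(
    list(sequences = sequences, annotations = annotations,
         centromeres = do.call(rbind, cens), library = library,
         spec = spec),
    class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "<annotated_genome> %d chromosome(s), %s bp, %d annotated repeat copies\n",
    length(x$sequences), format(genome_length(x), big.mark = ","),
    nrow(x$annotations)))
  invisible(x)
}

#' Total genome length
#' @param genome An `annotated_genome`.
#' @return Integer total length in bp.
#' @export
genome_length <- function(genome) {
  sum(Biostrings::width(genome$sequences))
}

#' Realized per-family base fractions of a genome
#'
#' Summed annotation interval lengths per family over the genome length;
#' by construction within +/- 10% relative of the spec for genomes of
#' 1 Mb and larger.
#'
#' @param genome An `annotated_genome`.
#' @return Named numeric vector of base fractions.
#' @export
family_base_fractions <- function(genome) {
  a <- genome$annotations
  if (nrow(a) == 0) return(setNames(numeric(0), character(0)))
  bp <- tapply(a$end - a$start + 1, a$family, sum)
  setNames(as.numeric(bp) / genome_length(genome), names(bp))
}

# -- internal block helpers --------------------------------------------------

# one tandem array block: `copies` head-to-tail monomers of one subfamily
array_block <- function(family, subfamily, monomer, copies) {
  list(family = family, subfamily = as.integer(subfamily),
       len = as.integer(nchar(monomer) * copies),
       seq = strrep(monomer, copies))
}

# split a family's copy budget into arrays of ~array_bp, cycling subfamilies
make_arrays <- function(f, lib, copies) {
  cpa <- max(1L, round(f$array_bp / f$monomer_length))
  n_arrays <- ceiling(copies / cpa)
  sizes <- split_largest_remainder(copies, rep(1 / n_arrays, n_arrays))
  subfam <- sample(rep_len(seq_len(f$n_subfamilies), n_arrays))
  lapply(seq_len(n_arrays), function(i) {
    array_block(f$name, subfam[i], lib[[subfam[i]]], sizes[i])
  })
}

# dispersed copies: one isolated monomer per block
monomer_blocks <- function(f, lib, copies) {
  subfam <- sample(rep_len(seq_len(f$n_subfamilies), copies))
  lapply(seq_len(copies), function(i) {
    array_block(f$name, subfam[i], lib[[subfam[i]]], 1L)
  })
}

# mark ~20% of a centromeric family's arrays for pericentromeric spill-over
spill_over_arrays <- function(arrays, fraction = 0.2) {
  n <- length(arrays)
  k <- round(fraction * n)
  spill <- rep(FALSE, n)
  if (k > 0) spill[sample.int(n, k)] <- TRUE
  spill
}

# lay blocks into a region of region_len bp, separated by random
# background gaps; returns sequence, block annotations (1-based, relative
# to region start) and total length
layout_region <- function(blocks, region_len, shuffle = TRUE) {
  region_len <- as.integer(region_len)
  block_bp <- sum(vapply(blocks, `[[`, integer(1), "len"))
  stopifnot(block_bp <= region_len)
  if (length(blocks) > 1 && shuffle) blocks <- sample(blocks)
  slack <- region_len - block_bp
  ngap <- length(blocks) + 1L
  gaps <- if (slack > 0) {
    as.integer(rmultinom(1, slack, rep(1, ngap)))
  } else rep(0L, ngap)
  pieces <- character(2 * length(blocks) + 1)
  starts <- integer(length(blocks))
  pos <- 0L
  for (i in seq_along(blocks)) {
    pieces[2 * i - 1] <- random_dna(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pieces[2 * i] <- blocks[[i]]$seq
    pos <- pos + blocks[[i]]$len
  }
  pieces[length(pieces)] <- random_dna(gaps[ngap])
  ann <- if (length(blocks) > 0) {
    tibble(
      chrom = NA_character_, start = starts,
      end = starts + vapply(blocks, `[[`, integer(1), "len") - 1L,
      family = vapply(blocks, `[[`, character(1), "family"),
      subfamily = vapply(blocks, `[[`, integer(1), "subfamily"))
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           family = character(), subfamily = integer())
  }
  list(seq = paste(pieces, collapse = ""), ann = ann, len = region_len)
}

# integer split of `total` proportional to `weights` (largest remainder)
split_largest_remainder <- function(total, weights) {
  weights <- weights / sum(weights)
  raw <- total * weights
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}
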