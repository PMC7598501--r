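test_that("empty family list gives pure random background", {
  g <- build_genome(genome_spec(50000L, families = list(),
                                n_chromosomes = 2L, seed = 1))
  expect_equal(genome_length(g), 50000L)
  expect_equal(nrow(g$annotations), 0)
  expect_equal(nrow(g$centromeres), 2)
})

test_that("realized family fractions land within 10% of spec", {
  g <- build_genome(genome_spec(2040000L, n_chromosomes = 2L, seed = 11))
  frac <- family_base_fractions(g)
  # 17% of 2,040,000 = 346,800 bp of major satellite
  major_bp <- frac[["major_sat"]] * genome_length(g)
  expect_lt(abs(major_bp - 346800) / 346800, 0.10)
  spec_frac <- vapply(g$spec$families, `[[`, numeric(1), "genome_fraction")
  expect_true(all(abs(frac[names(spec_frac)] - spec_frac) /
                    spec_frac < 0.10))
})

test_that("annotations never overlap and stay within chromosome ends", {
  g <- build_genome(genome_spec(1e6L, n_chromosomes = 3L, seed = 4))
  a <- g$annotations
  wl <- setNames(Biostrings::width(g$sequences), names(g$sequences))
  expect_true(all(a$start >= 1 & a$end <= wl[a$chrom]))
  for (ch in unique(a$chrom)) {
    x <- a[a$chrom == ch, ]
    x <- x[order(x$start), ]
    expect_true(all(x$start[-1] > x$end[-nrow(x)]))
  }
})

test_that("centromeric families concentrate inside centromeres with spill-over", {
  g <- build_genome(genome_spec(2e6L, n_chromosomes = 2L, seed = 9))
  a <- g$annotations[g$annotations$family == "major_sat", ]
  inside <- centroscope:::in_centromere(a, g$centromeres)
  bp <- a$end - a$start + 1
  frac_inside <- sum(bp[inside]) / sum(bp)
  # 20% of arrays spill into the pericentromere
  expect_gt(frac_inside, 0.65)
  expect_lt(frac_inside, 0.95)
  # spill-over arrays are adjacent to, not far from, the centromere
  out <- a[!inside, ]
  for (i in seq_len(nrow(out))) {
    ce <- g$centromeres[g$centromeres$chrom == out$chrom[i], ]
    gap <- max(0, max(ce$start - out$end[i], out$start[i] - ce$end))
    expect_lt(gap, 0.1 * genome_length(g) / 2)
  }
})

test_that("tandem unit lengths divide planted array lengths", {
  g <- build_genome(genome_spec(2e6L, n_chromosomes = 2L, seed = 9))
  a <- g$annotations[g$annotations$family == "rdna_5s", ]
  expect_gt(nrow(a), 0)
  # every planted 5S array is a whole number of 192-bp units (119 + 73)
  expect_true(all((a$end - a$start + 1) %% 192 == 0))
})

test_that("planted arrays are verbatim head-to-tail consensus copies", {
  g <- build_genome(genome_spec(8e5L, n_chromosomes = 1L, seed = 2))
  a <- g$annotations[g$annotations$family == "major_sat", ][1, ]
  mono <- g$library$major_sat[[a$subfamily]]
  planted <- as.character(Biostrings::subseq(
    g$sequences[[a$chrom]], a$start, a$end))
  copies <- (a$end - a$start + 1) / nchar(mono)
  expect_identical(planted, strrep(mono, copies))
})

test_that("genome construction is reproducible and fraction overflow errors", {
  s <- genome_spec(3e5L, n_chromosomes = 1L, seed = 5)
  g1 <- build_genome(s)
  g2 <- build_genome(s)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$annotations, g2$annotations)
  expect_error(
    genome_spec(1e5L, families = list(
      repeat_family_spec("a", 100L, 0.6),
      repeat_family_spec("b", 100L, 0.5))),
    "infeasible")
})
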