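test_that("read-count rounding reproduces the coverage arithmetic", {
  # 0.2 x 204e6 / 151 = 270198.7 -> ceil 270199 -> even 270200
  expect_identical(reads_for_coverage(204e6, 0.2, 151, paired = TRUE),
                   270200L)
  # 0.2 x 2,040,000 / 151 = 2701.99 -> ceil 2702, already even
  expect_identical(reads_for_coverage(2040000, 0.2, 151, paired = TRUE),
                   2702L)
  expect_identical(reads_for_coverage(2040000, 0.2, 151, paired = FALSE),
                   2702L)
  expect_error(reads_for_coverage(1e6, -0.1, 151), "coverage")
})

test_that("WGS simulation yields the requested reads with true origins", {
  g <- build_genome(genome_spec(3e5L, families = list(),
                                n_chromosomes = 2L, seed = 1))
  rs <- simulate_wgs_reads(g, coverage = 0.2, seed = 8)
  expect_identical(nrow(rs), reads_for_coverage(3e5, 0.2, 151, TRUE))
  expect_true(is_paired(rs))
  expect_identical(read_length(rs), 151L)
  # coverage 0 -> empty set
  expect_identical(nrow(simulate_wgs_reads(g, 0, seed = 1)), 0L)
})

test_that("read sequences equal genome substrings (reverse-complemented on minus)", {
  g <- build_genome(genome_spec(4e5L, n_chromosomes = 1L, seed = 3))
  rs <- simulate_wgs_reads(g, coverage = 0.05, seed = 2)
  idx <- seq_len(nrow(rs))
  for (i in idx) {
    s <- as.character(Biostrings::subseq(g$sequences[[rs$chrom[i]]],
                                         rs$start[i], rs$end[i]))
    if (rs$strand[i] == "-") s <- revcomp(s)
    expect_identical(s, rs$seq[i])
  }
  expect_true(all(rs$start >= 1))
  wl <- setNames(Biostrings::width(g$sequences), names(g$sequences))
  expect_true(all(rs$end <= wl[rs$chrom]))
})

test_that("simulation is bit-reproducible from the seed", {
  g <- build_genome(genome_spec(2e5L, families = list(),
                                n_chromosomes = 1L, seed = 1))
  expect_identical(simulate_wgs_reads(g, 0.1, seed = 9),
                   simulate_wgs_reads(g, 0.1, seed = 9))
  expect_false(identical(simulate_wgs_reads(g, 0.1, seed = 9)$seq,
                         simulate_wgs_reads(g, 0.1, seed = 10)$seq))
})

test_that("uniform occupancy model gives unit per-family enrichment", {
  g <- build_genome(genome_spec(6e5L, n_chromosomes = 1L, seed = 5))
  model <- occupancy_model(c(major_sat = 1), background_weight = 1,
                           occupied_fraction = 1)
  libs <- simulate_chip_input(g, model, n_reads = 8000, seed = 6)
  chip_frac <- mean(libs$chip$origin_family %in% "major_sat")
  input_frac <- mean(libs$input$origin_family %in% "major_sat")
  expect_lt(abs(chip_frac / input_frac - 1), 0.15)
})

test_that("ChIP origin ratios converge to the closed-form expectation", {
  g <- build_genome(genome_spec(1e6L, n_chromosomes = 1L, seed = 7))
  model <- occupancy_model(c(major_sat = 4), background_weight = 1,
                           occupied_fraction = 0.5)
  set.seed(13)
  wt <- chip_weight_table(g, model)
  expected <- expected_family_enrichment(g, wt)[["major_sat"]]
  expect_gt(expected, 1.3)  # weight 4 on half the centromeric arrays
  libs <- simulate_chip_input(g, model, n_reads = 20000, seed = 13)
  chip_frac <- mean(libs$chip$origin_family %in% "major_sat")
  input_frac <- mean(libs$input$origin_family %in% "major_sat")
  expect_lt(abs(chip_frac / input_frac - expected) / expected, 0.15)
})

test_that("degenerate occupancy models and empty libraries are handled", {
  expect_error(occupancy_model(c(major_sat = 0), background_weight = 0),
               "degenerate")
  g <- build_genome(genome_spec(1e5L, families = list(),
                                n_chromosomes = 1L, seed = 1))
  model <- occupancy_model(c(major_sat = 2))
  libs <- simulate_chip_input(g, model, n_reads = 0)
  expect_identical(nrow(libs$chip), 0L)
  expect_identical(nrow(libs$input), 0L)
})
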