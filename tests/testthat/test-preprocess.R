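make_qual_read <- function(id, qualities, base = "A") {
  tibble::tibble(id = id, seq = strrep(base, length(qualities)),
                 qual = intToUtf8(qualities + 33L))
}

test_that("quality filter applies inclusive boundaries on both counts", {
  pass <- make_qual_read("pass", c(rep(9L, 5), rep(30L, 95)))
  fail <- make_qual_read("fail", c(rep(9L, 6), rep(30L, 94)))
  clean <- make_qual_read("clean", rep(30L, 100))
  rs <- read_set(rbind(clean, pass, fail))
  out <- quality_filter(rs, cutoff = 10L, pass_fraction = 0.95)
  # 95/100 bases >= 10 passes (boundary inclusive); 94/100 does not
  expect_identical(out$id, c("clean", "pass"))
  # membership changes, content never does
  expect_identical(out$seq, rs$seq[match(out$id, rs$id)])
  expect_identical(quality_filter(rs, 10L, 0)$id, rs$id)
  expect_identical(nrow(quality_filter(read_set(
    tibble::tibble(id = character(), seq = character(),
                   qual = character())), 10L, 0.95)), 0L)
})

test_that("trimming truncates from the 3' end and drops short reads", {
  rs <- read_set(tibble::tibble(
    id = c("long", "exact", "short"),
    seq = c(random_dna(160), random_dna(151), random_dna(120))))
  out <- trim_to_length(rs, 151L)
  expect_identical(out$id, c("long", "exact"))
  expect_identical(out$seq[out$id == "long"],
                   substr(rs$seq[rs$id == "long"], 1, 151))
  expect_identical(out$seq[out$id == "exact"],
                   rs$seq[rs$id == "exact"])
  expect_true(all(nchar(out$qual) == 151))
})

test_that("filtering and trimming are idempotent", {
  set.seed(4)
  len <- sample(140:170, 20, replace = TRUE)
  rs <- read_set(tibble::tibble(
    id = sprintf("r%02d", 1:20),
    seq = vapply(len, random_dna, character(1)),
    qual = vapply(len, function(l) {
      intToUtf8(sample(2:40, l, replace = TRUE) + 33L)
    }, character(1))))
  f1 <- quality_filter(rs, 10L, 0.9)
  expect_identical(quality_filter(f1, 10L, 0.9), f1)
  t1 <- trim_to_length(rs, 151L)
  expect_identical(trim_to_length(t1, 151L), t1)
})

test_that("interlacing orders intact pairs and drops orphans", {
  rs <- read_set(tibble::tibble(
    id = c("a/1", "a/2", "b/1", "b/2", "c/1", "c/2"),
    seq = replicate(6, random_dna(10)),
    pair_id = rep(c("a", "b", "c"), each = 2),
    mate = rep(c(1L, 2L), 3)))
  out <- interlace_pairs(rs)
  expect_identical(out$id, c("a/1", "a/2", "b/1", "b/2", "c/1", "c/2"))
  # one mate of pair b removed upstream -> whole pair dropped
  out2 <- interlace_pairs(rs[rs$id != "b/2", ])
  expect_identical(out2$id, c("a/1", "a/2", "c/1", "c/2"))
  unpaired <- read_set(tibble::tibble(id = "x", seq = "ACGT"))
  expect_error(interlace_pairs(unpaired), "not paired")
})

test_that("subsampling hits the coverage formula, keeps pairs and reproduces", {
  g <- build_genome(genome_spec(3e5L, families = list(),
                                n_chromosomes = 1L, seed = 1))
  rs <- simulate_wgs_reads(g, coverage = 0.4, seed = 2)
  out <- subsample_to_coverage(rs, 3e5, 0.2, 151L, seed = 3)
  expect_identical(nrow(out), reads_for_coverage(3e5, 0.2, 151, TRUE))
  # pairing preserved: both mates or neither
  expect_true(all(table(out$pair_id) == 2))
  out2 <- subsample_to_coverage(rs, 3e5, 0.2, 151L, seed = 3)
  expect_identical(sort(out$id), sort(out2$id))
  expect_error(subsample_to_coverage(rs, 3e5, 0.45, 151L, seed = 1),
               "insufficient")
  expect_warning(subsample_to_coverage(rs, 3e5, 0.005, 151L, seed = 1),
                 "recommended")
})
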