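test_that("identical reads and reverse complements form edges", {
  s <- random_dna(151)
  rs <- read_set(tibble::tibble(id = c("a", "b", "c"),
                                seq = c(s, s, revcomp(s))))
  edges <- build_similarity_graph(rs)
  expect_identical(nrow(edges), 3L)
  ab <- edges[edges$read_a == "a" & edges$read_b == "b" |
                edges$read_a == "b" & edges$read_b == "a", ]
  expect_equal(ab$identity, 1)
  expect_equal(ab$overlap_fraction, 1)
  expect_identical(ab$orientation, "forward")
  ac <- edges[edges$read_b == "c" & edges$read_a == "a", ]
  expect_identical(ac$orientation, "reverse")
  expect_equal(ac$identity, 1)
})

test_that("the k-mer prefilter reproduces the exhaustive edge set", {
  mono <- random_dna(360)
  rs <- rbind_read_sets(
    sample_array_reads(mono, 60, sub_rate = 0.025, seed = 1),
    background_reads(30, seed = 2))
  fast <- build_similarity_graph(rs)
  full <- build_similarity_graph(rs, exhaustive = TRUE)
  expect_identical(edge_keys(fast), edge_keys(full))
})

test_that("edgeless read sets cluster to all singletons", {
  rs <- background_reads(25, seed = 3)
  edges <- build_similarity_graph(rs)
  cl <- cluster_reads(edges, rs)
  expect_identical(cl$summary$n_clusters, 0L)
  expect_identical(cl$summary$singleton_reads, 25L)
  expect_identical(cl$summary$clustered_reads, 0L)
})

test_that("clusters partition reads and ranks are monotone", {
  mono1 <- random_dna(360); mono2 <- random_dna(360)
  rs <- rbind_read_sets(
    sample_array_reads(mono1, 50, sub_rate = 0.02, seed = 4, prefix = "s1"),
    sample_array_reads(mono2, 25, sub_rate = 0.02, seed = 5, prefix = "s2"),
    background_reads(40, seed = 6))
  cl <- cluster_reads(build_similarity_graph(rs), rs)
  s <- cl$summary
  expect_identical(s$clustered_reads + s$singleton_reads, s$total_reads)
  expect_equal(s$clustered_fraction, s$clustered_reads / s$total_reads)
  members <- unlist(cl$clusters$members)
  expect_identical(anyDuplicated(members), 0L)
  expect_true(all(diff(cl$clusters$size) <= 0))
  expect_identical(cl$clusters$cluster_id,
                   paste0("CL", seq_len(nrow(cl$clusters))))
})

test_that("top clusters recover planted families with high origin purity", {
  g <- small_test_genome(seed = 21)
  rs <- simulate_wgs_reads(g, coverage = 0.3, seed = 22)
  cl <- cluster_reads(build_similarity_graph(rs), rs)
  top <- cl$clusters[1:3, ]
  dominant <- vapply(top$members, function(m) {
    fam <- rs$origin_family[match(m, rs$id)]
    tab <- sort(table(fam), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  purity <- vapply(top$members, function(m) {
    fam <- rs$origin_family[match(m, rs$id)]
    max(table(fam)) / length(m)
  }, numeric(1))
  expect_setequal(dominant, c("satA", "satB", "mobC"))
  expect_true(all(purity >= 0.9))
})

test_that("genome proportion arithmetic matches the published cluster shares", {
  # a 12,159-read cluster of 270,200 analyzed reads is 4.5% of the genome
  expect_equal(round(genome_proportion(12159, 270200), 3), 0.045)
  expect_equal(genome_proportion(c(12159, 10808, 8376, 5944), 270200) |>
                 sum() |> round(3), 0.138)
  expect_error(genome_proportion(10, 0), "total_reads")
  expect_error(genome_proportion(0, 100), "count")
})

test_that("cluster annotation picks the planted library label", {
  g <- small_test_genome(seed = 31)
  rs <- simulate_wgs_reads(g, coverage = 0.3, seed = 32)
  cl <- cluster_reads(build_similarity_graph(rs), rs)
  lib <- c(satA = g$library$satA[[1]], satB = g$library$satB[[1]],
           mobC = g$library$mobC[[1]])
  top_label <- vapply(cl$clusters$members[1:3], annotate_cluster,
                      character(1), rs = rs, library = lib)
  truth <- vapply(cl$clusters$members[1:3], function(m) {
    names(sort(table(rs$origin_family[match(m, rs$id)]),
               decreasing = TRUE))[1]
  }, character(1))
  expect_identical(unname(top_label), truth)
  bg <- background_reads(10, seed = 33)
  expect_identical(annotate_cluster(bg$id, bg, lib), "unknown")
  expect_error(annotate_cluster(bg$id, bg, character(0)), "non-empty")
})

test_that("identical consensuses tie to the first subfamily label", {
  mono <- random_dna(360)
  rs <- sample_array_reads(mono, 30, seed = 7)
  prof <- subfamily_proportions(rs$id, rs,
                                c(sub2 = mono, sub1 = mono, sub3 = mono))
  expect_equal(unname(prof$proportions["sub1"]), 1)
  expect_equal(prof$unassigned_fraction, 0)
  expect_equal(sum(prof$proportions) + prof$unassigned_fraction, 1,
               tolerance = 1e-9)
  expect_error(subfamily_proportions(character(0), rs, c(a = mono)),
               "non-empty")
})
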