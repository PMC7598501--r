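test_that("enrichment ratio arithmetic reproduces the published rows", {
  cfg <- mapper_config(n_sampled_reads = 1e6L)
  chip <- c(CL3 = 42004L, CL48 = 10565L, CL141 = 488L, CLx = 0L,
            CLy = 5L)
  input <- c(CL3 = 38140L, CL48 = 5052L, CL141 = 158L, CLx = 7L,
             CLy = 0L)
  rec <- compute_enrichment(chip, input, cfg)
  expect_equal(round_half_up(rec$ratio[rec$cluster_id == "CL3"], 2), 1.10)
  expect_equal(round_half_up(rec$ratio[rec$cluster_id == "CL48"], 2), 2.09)
  expect_equal(round_half_up(rec$ratio[rec$cluster_id == "CL141"], 2),
               3.09)
  # zero ChIP hits over positive input -> 0; zero input -> undefined NA
  expect_equal(rec$ratio[rec$cluster_id == "CLx"], 0)
  expect_true(is.na(rec$ratio[rec$cluster_id == "CLy"]))
  expect_error(compute_enrichment(chip, input[c(1, 2, 3, 5, 4)], cfg),
               "same clusters")
})

test_that("unequal library sizes are refused unless scaling is requested", {
  chip <- c(CL1 = 100L); input <- c(CL1 = 50L)
  expect_error(compute_enrichment(chip, input, chip_total = 2e6,
                                  input_total = 1e6),
               "unequal")
  rec <- compute_enrichment(chip, input, scale_by_library_size = TRUE,
                            chip_total = 2e6, input_total = 1e6)
  expect_equal(rec$ratio, (100 / 2e6) / (50 / 1e6))
})

test_that("mean enrichment is the arithmetic mean of defined ratios", {
  rec <- compute_enrichment(c(a = 1L, b = 3L, c = 4L),
                            c(a = 1L, b = 1L, c = 0L))
  expect_equal(mean_enrichment(rec), 2)  # {1, 3}, NA excluded
  single <- compute_enrichment(c(a = 7L), c(a = 2L))
  expect_equal(mean_enrichment(single), 3.5)
  none <- compute_enrichment(c(a = 7L), c(a = 0L))
  expect_error(mean_enrichment(none), "undefined")
  # brute-force mean over many synthetic records
  set.seed(9)
  ch <- setNames(rpois(1000, 200), paste0("CL", 1:1000))
  inp <- setNames(rpois(1000, 150) + 1L, paste0("CL", 1:1000))
  rec <- compute_enrichment(ch, inp)
  expect_equal(mean_enrichment(rec), sum(ch / inp) / 1000)
})

test_that("dual selection criteria use strict ratio bounds and precedence", {
  cfg <- mapper_config(n_sampled_reads = 1e6L)
  rec <- compute_enrichment(
    c(CL48 = 10565L, CL141 = 488L, CLb = 1000L, CLc = 9L),
    c(CL48 = 5052L, CL141 = 158L, CLb = 500L, CLc = 3L))
  sel <- select_candidates(rec, cfg)
  # CL48 meets both criteria; the high-abundance block claims it
  expect_identical(sel$high_abundance$cluster_id, "CL48")
  # ratio 3.09 with 488 hits (>= 100) is enriched
  expect_identical(sel$enriched$cluster_id, "CL141")
  # CLb: ratio exactly 2.00 is not > 2; CLc: 9 hits < 100
  expect_false("CLb" %in% unlist(lapply(sel, `[[`, "cluster_id")))
  expect_false("CLc" %in% unlist(lapply(sel, `[[`, "cluster_id")))
  cfg2 <- mapper_config(n_sampled_reads = 1e6L, precedence = "enriched")
  sel2 <- select_candidates(rec, cfg2)
  expect_identical(sel2$enriched$cluster_id, c("CL48", "CL141"))
  expect_identical(nrow(sel2$high_abundance), 0L)
})

test_that("selection thresholds scale with the analyzed read count", {
  th <- selection_thresholds(1e6)
  expect_equal(th$enriched_min_hits, 100)
  expect_equal(th$high_abundance_min_hits, 10000)
})

test_that("read mapping assigns one best hit with threshold monotonicity", {
  g <- small_test_genome(seed = 41)
  rs <- simulate_wgs_reads(g, coverage = 0.3, seed = 42)
  cl <- cluster_reads(build_similarity_graph(rs), rs)
  # a read identical to a CL1 member maps to CL1 and nowhere else
  probe <- read_set(tibble::tibble(
    id = "probe", seq = rs$seq[match(cl$clusters$members[[1]][1], rs$id)]))
  cfg <- mapper_config(n_sampled_reads = 1000L, top_n_clusters = 50L)
  hits <- map_reads_to_clusters(probe, cl$clusters, rs, cfg)
  expect_identical(unname(hits["CL1"]), 1L)
  expect_identical(sum(hits), 1L)
  # random background reads produce (essentially) no qualifying hits
  bg <- background_reads(300, seed = 43)
  bg_hits <- map_reads_to_clusters(bg, cl$clusters, rs, cfg)
  expect_lte(sum(bg_hits), 1)
  # raising the bit-score threshold never increases any count
  chip <- simulate_chip_input(g, occupancy_model(c(satA = 4),
                                                 occupied_fraction = 0.5),
                              n_reads = 1500, seed = 44)$chip
  h30 <- map_reads_to_clusters(chip, cl$clusters, rs,
                               mapper_config(1500L, 30, 50L))
  h150 <- map_reads_to_clusters(chip, cl$clusters, rs,
                                mapper_config(1500L, 150, 50L))
  expect_true(all(h150 <= h30))
  expect_lte(sum(h30), nrow(chip))
  expect_error(map_reads_to_clusters(chip, cl$clusters[0, ], rs, cfg),
               "empty cluster list")
})

test_that("the report rounds ratios half-up and handles empty selections", {
  cfg <- mapper_config(n_sampled_reads = 1e6L)
  rec <- compute_enrichment(c(CL48 = 10565L, CL141 = 488L),
                            c(CL48 = 5052L, CL141 = 158L))
  rep <- enrichment_report(rec, cfg, annotations = c(CL48 = "tandem repeat"))
  expect_identical(rep$criteria, c("high_abundance", "enriched"))
  expect_equal(rep$ratio, c(2.09, 3.09))
  expect_identical(rep$annotation[1], "tandem repeat")
  empty <- enrichment_report(compute_enrichment(c(a = 1L), c(a = 2L)), cfg)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("criteria", "cluster", "chip_hits", "input_hits",
                     "ratio", "annotation"))
})

test_that("the shipped published hit-count table is internally consistent", {
  tab <- cench3_cluster_hits()
  expect_identical(nrow(tab), 28L)
  expect_true(all(tab$chip_hits > 0 & tab$input_hits > 0))
  expect_identical(sum(tab$criteria == "high_abundance"), 8L)
})
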