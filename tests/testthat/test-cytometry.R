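test_that("thresholding handles constant, fixed and bimodal channels", {
  p <- intensity_profile(1:100, list(zero = rep(0, 100),
                                     pos = c(rep(0, 40), rep(5, 60))))
  expect_false(any(threshold_profile(p, "zero", "fixed", 0)))
  fix <- threshold_profile(p, "pos", "fixed", 0)
  expect_identical(sum(fix), 60L)
  expect_error(threshold_profile(p, "nope"), "unknown channel")
  # isodata separates two well-split modes with <= 1% mismatch
  set.seed(2)
  truth <- rep(c(FALSE, TRUE), c(700, 300))
  x <- ifelse(truth, rnorm(1000, 100, 1), rnorm(1000, 10, 1))
  bp <- intensity_profile(1:1000, list(sig = pmax(0, x)))
  pres <- threshold_profile(bp, "sig", "isodata")
  expect_lte(mean(pres != truth), 0.01)
  t <- attr(pres, "threshold")
  expect_gt(t, 10); expect_lt(t, 100)
})

test_that("domain detection merges small gaps and drops small runs", {
  pos <- 1:100
  pres <- rep(FALSE, 100)
  pres[11:20] <- TRUE; pres[23:32] <- TRUE; pres[60:61] <- TRUE
  # no merging: three runs; min_domain drops the 2-wide run
  d0 <- detect_domains(pres, pos)
  expect_identical(nrow(d0), 3L)
  # the gap 21-22 spans distance 3 (end 20 to start 23): a min_gap of 3
  # does not bridge it (strict), a min_gap of 4 does
  d1 <- detect_domains(pres, pos, min_gap = 3, min_domain = 5)
  expect_identical(nrow(d1), 2L)
  d2 <- detect_domains(pres, pos, min_gap = 4, min_domain = 5)
  expect_identical(nrow(d2), 1L)
  expect_equal(c(d2$start, d2$end), c(11, 32))
  expect_identical(nrow(detect_domains(rep(FALSE, 10), 1:10)), 0L)
  # invariant to padding absent positions at either end
  d3 <- detect_domains(c(FALSE, FALSE, pres, FALSE), c(-1:0, pos, 101),
                       min_gap = 4, min_domain = 5)
  expect_equal(d2, d3)
})

test_that("centromere measurement recovers the planted extent", {
  p <- simulate_profile(intensity_profile_spec(1000L, 0.435, 4L, seed = 2))
  m <- centromere_measurement(p)
  expect_false(m$failed)
  expect_lt(abs(m$ratio - 0.435), 0.005)
  expect_identical(m$n_domains, 4L)
  # cen channel covering the whole extent -> ratio 1
  full <- intensity_profile(1:50, list(dna = rep(9, 50),
                                       cenh3 = rep(9, 50)))
  expect_equal(centromere_measurement(full)$ratio, 1)
  # no domain -> measurement-failed signal, not an error
  blank <- intensity_profile(1:50, list(dna = rep(9, 50),
                                        cenh3 = rep(0, 50)))
  expect_true(centromere_measurement(blank, method = "fixed")$failed)
})

test_that("the ratio is invariant under uniform coordinate rescaling", {
  p <- simulate_profile(intensity_profile_spec(800L, 0.4, 3L, seed = 6))
  m1 <- centromere_measurement(p)
  p2 <- intensity_profile(p$position * 2.7,
                          list(dna = p$dna, cenh3 = p$cenh3))
  m2 <- centromere_measurement(p2)
  expect_equal(m1$ratio, m2$ratio)
  expect_identical(m1$n_domains, m2$n_domains)
})

test_that("overlap fraction is symmetric and exact on planted fibers", {
  p <- simulate_profile(intensity_profile_spec(
    1000L, channel_overlap = 0.75, mode = "fiber", seed = 3))
  ov <- overlap_fraction(p, "cenh3", "satellite")
  expect_equal(ov$overlap_fraction, 0.75)
  ov2 <- overlap_fraction(p, "satellite", "cenh3")
  expect_equal(ov$overlap_fraction, ov2$overlap_fraction)
  expect_lte(ov$overlap_fraction, min(ov$fraction_a, ov$fraction_b))
  same <- intensity_profile(1:10, list(a = rep(3, 10), b = rep(5, 10)))
  expect_equal(overlap_fraction(same, "a", "b")$overlap_fraction, 1)
  disj <- intensity_profile(1:10, list(a = rep(c(1, 0), 5),
                                       b = rep(c(0, 1), 5)))
  expect_equal(overlap_fraction(disj, "a", "b")$overlap_fraction, 0)
  none <- intensity_profile(1:10, list(a = rep(0, 10), b = rep(0, 10)))
  expect_error(overlap_fraction(none, "a", "b"), "undefined")
})

test_that("measurement summaries report mean and sample sd", {
  ms <- lapply(c(0.4, 0.5), function(r) {
    structure(list(failed = FALSE, ratio = r),
              class = "chromosome_measurement")
  })
  s <- summarize_measurements(ms)
  expect_equal(s$mean_ratio, 0.45)
  expect_equal(s$sd_ratio, sd(c(0.4, 0.5)), tolerance = 1e-12)
  expect_warning(s1 <- summarize_measurements(ms[1]), "single")
  expect_equal(s1$sd_ratio, 0)
  expect_error(summarize_measurements(list()), "no measurements")
})
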