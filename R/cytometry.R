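#' Threshold an intensity channel
#'
#' Computes a presence mask for one channel of an intensity profile.
#' The `"isodata"` method is the iterative intermeans algorithm (the
#' algorithm behind ImageJ's default auto-threshold): starting from the
#' overall mean, the threshold is updated to the midpoint of the means
#' below and above it until stable.  Presence is intensity strictly
#' greater than the threshold.  With `method = "fixed"` the supplied
#' threshold is used directly; a fixed threshold of 0 marks every
#' position with positive intensity.
#'
#' @param p An [intensity_profile()].
#' @param channel Channel name.
#' @param method `"isodata"` or `"fixed"`.
#' @param value Threshold for the fixed method.
#' @return Logical presence vector with the threshold attached as
#'   attribute `"threshold"`.
#' @export
threshold_profile <- function(p, channel, method = c("isodata", "fixed"),
                              value = 0) {
  method <- match.arg(method)
  if (!channel %in% profile_channels(p)) {
    stop("unknown channel: ", channel)
  }
  x <- p[[channel]]
  t <- if (method == "fixed") value else isodata_threshold(x)
  structure(x > t, threshold = t)
}

# iterative intermeans threshold; constant signals get a threshold just
# below the constant so positive constants count as present
isodata_threshold <- function(x, tol = 1e-6, max_iter = 200) {
  if (length(x) == 0) return(0)
  if (diff(range(x)) < tol) return(min(x) - tol)
  t <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) break
    t <- t_new
  }
  t
}

#' Detect signal domains along a profile
#'
#' Maximal runs of present positions, after merging runs separated by
#' gaps shorter than `min_gap` and discarding runs spanning less than
#' `min_domain` (both in position units).  Intervals are disjoint and
#' ordered; leading or trailing absent positions do not affect the
#' result.
#'
#' @param presence Logical presence vector (e.g. from
#'   [threshold_profile()]).
#' @param positions Numeric coordinates aligned with `presence`.
#' @param min_gap Gaps narrower than this are bridged.
#' @param min_domain Domains narrower than this are dropped.
#' @return Tibble of `start`, `end` domain coordinates.
#' @export
detect_domains <- function(presence, positions, min_gap = 0,
                           min_domain = 0) {
  stopifnot(length(presence) == length(positions))
  presence <- as.logical(presence)  # drop threshold attribute for rle()
  empty <- tibble(start = numeric(), end = numeric())
  if (!any(presence)) return(empty)
  r <- rle(presence)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- tibble(start = positions[starts_i[r$values]],
                 end = positions[ends_i[r$values]])
  # merge across small gaps
  if (nrow(runs) > 1 && min_gap > 0) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)]
      if (gap < min_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs[runs$end - runs$start >= min_domain, ]
}

#' Measure centromere extent on a chromosome profile
#'
#' The chromosome is the span of the DNA-stain presence; the centromere
#' length is the distance between the outer edges of the first and last
#' CenH3 domain (inclusive of the outermost domains, so a single-domain
#' dot-like centromere has the extent of that domain rather than zero).
#' The ratio of the two is unit-free and thus comparable across spreads
#' with different condensation.
#'
#' @param p An [intensity_profile()].
#' @param dna_channel,cen_channel Channel names.
#' @param method,value Thresholding method and fixed value, per channel
#'   (see [threshold_profile()]).
#' @param min_gap,min_domain Domain-calling parameters in position
#'   units; the defaults bridge gaps below 2% and drop domains below 1%
#'   of the chromosome length.
#' @return A `chromosome_measurement`: list with `chromosome_length`,
#'   `centromere_length`, `ratio`, `n_domains`; `NULL` fields and a
#'   `failed` flag when no CenH3 domain is detected.
#' @export
centromere_measurement <- function(p, dna_channel = "dna",
                                   cen_channel = "cenh3",
                                   method = "isodata", value = 0,
                                   min_gap = NULL, min_domain = NULL) {
  dna <- threshold_profile(p, dna_channel, method, value)
  cen <- threshold_profile(p, cen_channel, method, value)
  pos <- p$position
  if (!any(dna)) {
    return(structure(list(failed = TRUE), class = "chromosome_measurement"))
  }
  chrom_len <- max(pos[dna]) - min(pos[dna])
  if (is.null(min_gap)) min_gap <- 0.02 * chrom_len
  if (is.null(min_domain)) min_domain <- 0.01 * chrom_len
  dom <- detect_domains(cen, pos, min_gap, min_domain)
  if (nrow(dom) == 0) {
    return(structure(list(failed = TRUE, chromosome_length = chrom_len),
                     class = "chromosome_measurement"))
  }
  cen_len <- dom$end[nrow(dom)] - dom$start[1]
  structure(
    list(failed = FALSE, chromosome_length = chrom_len,
         centromere_length = cen_len, ratio = cen_len / chrom_len,
         n_domains = nrow(dom)),
    class = "chromosome_measurement")
}

#' Two-channel signal overlap on a fiber profile
#'
#' After thresholding both channels, the overlap fraction is the number
#' of co-positive positions over the number of positions where at least
#' one channel is positive (the signal-bearing span of the measured
#' fiber).  Per-channel fractions use the same denominator, so the
#' overlap can never exceed either.
#'
#' @param p An [intensity_profile()].
#' @param channel_a,channel_b Channel names.
#' @param method,value Thresholding method and fixed value.
#' @return An `overlap_result`: list with `fiber_length_measured`
#'   (positions with any signal), `fraction_a`, `fraction_b`,
#'   `overlap_fraction`.
#' @export
overlap_fraction <- function(p, channel_a, channel_b, method = "fixed",
                             value = 0) {
  a <- threshold_profile(p, channel_a, method, value)
  b <- threshold_profile(p, channel_b, method, value)
  union <- a | b
  if (!any(union)) {
    stop("undefined overlap: no position carries any signal")
  }
  structure(
    list(fiber_length_measured = sum(union),
         fraction_a = sum(a) / sum(union),
         fraction_b = sum(b) / sum(union),
         overlap_fraction = sum(a & b) / sum(union)),
    class = "overlap_result")
}

#' Summarize chromosome measurements
#'
#' Mean and sample standard deviation of centromere/chromosome ratios,
#' optionally per chromosome group.  A single measurement reports sd 0
#' with a warning.  Failed measurements are dropped.
#'
#' @param measurements List of `chromosome_measurement` objects.
#' @param groups Optional chromosome labels aligned with
#'   `measurements`.
#' @return Tibble with `group`, `n`, `mean_ratio`, `sd_ratio`.
#' @export
summarize_measurements <- function(measurements, groups = NULL) {
  if (length(measurements) == 0) stop("no measurements to summarize")
  ok <- !vapply(measurements, `[[`, logical(1), "failed")
  ratios <- vapply(measurements[ok], `[[`, numeric(1), "ratio")
  if (is.null(groups)) {
    groups <- rep("all", length(measurements))
  }
  groups <- groups[ok]
  out <- lapply(split(ratios, groups), function(r) {
    s <- if (length(r) < 2) {
      warning("single measurement: sample sd reported as 0")
      0
    } else {
      sd(r)
    }
    c(n = length(r), mean_ratio = mean(r), sd_ratio = s)
  })
  stats <- do.call(rbind, out)
  tibble(group = rownames(stats), n = as.integer(unname(stats[, "n"])),
         mean_ratio = unname(stats[, "mean_ratio"]),
         sd_ratio = unname(stats[, "sd_ratio"]))
}
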