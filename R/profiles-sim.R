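#' Specify a simulated fluorescence line profile
#'
#' Two profile geometries are generated.  In `"chromosome"` mode the
#' DNA-stain channel is positive along the whole chromosome axis and the
#' CenH3 channel is positive in `n_domains` disjoint blocks (the
#' bead-like metapolycentromere pattern) whose outermost-edge span
#' relative to the axis equals `centromere_fraction`.  In `"fiber"` mode
#' two channels (CenH3 and a satellite FISH probe) are planted on an
#' extended chromatin fiber so that the co-positive fraction of the
#' signal-bearing span equals `channel_overlap`.
#'
#' @param n_positions Number of profile positions (>= 10 * n_domains).
#' @param centromere_fraction Planted relative centromere extent, (0, 1).
#' @param n_domains Number of CenH3 domains (>= 1); 1 gives the dot-like
#'   pattern of a minute chromosome.
#' @param channel_overlap Planted co-positive fraction for fiber mode,
#'   in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (intensities are
#'   clipped at 0 after adding noise).
#' @param seed Integer seed.
#' @param mode `"chromosome"` or `"fiber"`.
#' @return An `intensity_profile_spec` object.
#' @export
intensity_profile_spec <- function(n_positions, centromere_fraction = 0.435,
                                   n_domains = 4L, channel_overlap = 0.75,
                                   noise_sd = 0, seed = 1L,
                                   mode = c("chromosome", "fiber")) {
  mode <- match.arg(mode)
  n_positions <- as.integer(n_positions)
  n_domains <- as.integer(n_domains)
  if (n_domains < 1L) stop("invalid spec: n_domains must be >= 1")
  if (n_positions < 10L * n_domains) {
    stop("invalid spec: n_positions must be >= 10 * n_domains")
  }
  if (centromere_fraction <= 0 || centromere_fraction >= 1) {
    stop("invalid spec: centromere_fraction must be in (0, 1)")
  }
  if (channel_overlap < 0 || channel_overlap > 1) {
    stop("invalid spec: channel_overlap must be in [0, 1]")
  }
  if (noise_sd < 0) stop("invalid spec: noise_sd must be >= 0")
  structure(
    list(n_positions = n_positions,
         centromere_fraction = centromere_fraction, n_domains = n_domains,
         channel_overlap = channel_overlap, noise_sd = noise_sd,
         seed = as.integer(seed), mode = mode),
    class = "intensity_profile_spec")
}

#' Multi-channel intensity profile container
#'
#' Per-position fluorescence intensities along a chromosome axis or
#' chromatin fiber: a tibble with a strictly increasing `position`
#' column (arbitrary physical units) and one non-negative intensity
#' column per channel.
#'
#' @param positions Strictly increasing numeric coordinates.
#' @param channels Named list or data frame of per-position intensities.
#' @return An `intensity_profile` tibble.
#' @export
intensity_profile <- function(positions, channels) {
  channels <- as_tibble(as.list(channels))
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (any(vapply(channels, length, integer(1)) != length(positions))) {
    stop("all channels must match the number of positions")
  }
  out <- tibble(position = as.numeric(positions))
  out <- cbind(out, channels)
  out <- as_tibble(out)
  class(out) <- c("intensity_profile", class(tibble()))
  out
}

#' Channel names of an intensity profile
#' @param p An [intensity_profile()].
#' @return Character vector of channel column names.
#' @export
profile_channels <- function(p) setdiff(names(p), "position")

#' Simulate a fluorescence line profile
#'
#' See [intensity_profile_spec()] for the two geometries.  The planted
#' signal level is 100 intensity units; Gaussian noise of `noise_sd` is
#' added and intensities are clipped at zero so that presence can be
#' called as intensity > 0 at zero noise.
#'
#' @param spec An [intensity_profile_spec()].
#' @return An [intensity_profile()]; chromosome mode has channels `dna`
#'   and `cenh3`, fiber mode `cenh3` and `satellite`.  The planted
#'   presence masks are attached as attribute `truth`.
#' @export
simulate_profile <- function(spec) {
  stopifnot(inherits(spec, "intensity_profile_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_positions
    if (spec$mode == "chromosome") {
      span <- round(spec$centromere_fraction * n)
      d <- spec$n_domains
      if (span < 2 * d - 1) stop("invalid spec: centromere span too small ",
                                 "for the requested number of domains")
      widths <- split_largest_remainder(span, rep(1, 2 * d - 1))
      # segments alternate block, gap, block, ...; first and last are blocks
      offset <- sample.int(n - span + 1, 1)
      mask <- logical(n)
      pos <- offset
      for (s in seq_len(2 * d - 1)) {
        if (s %% 2 == 1) mask[pos:(pos + widths[s] - 1)] <- TRUE
        pos <- pos + widths[s]
      }
      channels <- list(dna = rep(100, n), cenh3 = ifelse(mask, 100, 0))
      truth <- list(dna = rep(TRUE, n), cenh3 = mask)
    } else {
      k <- round(spec$channel_overlap * n)
      a_only <- ceiling((n - k) / 2)
      mask_a <- c(rep(TRUE, k + a_only), rep(FALSE, n - k - a_only))
      mask_b <- c(rep(TRUE, k), rep(FALSE, a_only),
                  rep(TRUE, n - k - a_only))
      channels <- list(cenh3 = ifelse(mask_a, 100, 0),
                       satellite = ifelse(mask_b, 100, 0))
      truth <- list(cenh3 = mask_a, satellite = mask_b)
    }
    if (spec$noise_sd > 0) {
      channels <- lapply(channels, function(x) {
        pmax(0, x + rnorm(n, sd = spec$noise_sd))
      })
    }
    out <- intensity_profile(seq_len(n), channels)
    attr(out, "truth") <- truth
    out
  })
}
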