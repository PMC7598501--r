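#' Counts per million reads mapped
#'
#' `hit_count / library_size * 1e6`.  Linear in the hit count and
#' invariant to scaling both arguments by the same factor.
#'
#' @param hit_count Reads mapped to the gene (>= 0).
#' @param library_size Total reads in the library (> 0).
#' @return Numeric CPM value(s).
#' @export
cpm <- function(hit_count, library_size) {
  if (any(library_size <= 0)) {
    stop("invalid argument: library_size must be > 0")
  }
  if (any(hit_count < 0)) stop("invalid argument: hit_count must be >= 0")
  hit_count / library_size * 1e6
}

#' Aggregate CPM across runs and biological replicates
#'
#' Two-stage averaging: CPM is computed per sequencing run, averaged
#' within each biological replicate, and the mean and sample standard
#' deviation are then taken across replicates per sample label.  The
#' replicate is the error unit (error bars across biological
#' replicates), which is why runs are not pooled.
#'
#' @param samples Data frame with columns `label`, `replicate`, `run`,
#'   `hit_count`, `library_size` (e.g. four runs for each of two or
#'   three replicates per tissue).
#' @return Tibble with `label`, `mean_cpm`, `sd_cpm`, `n_replicates`,
#'   one row per label.  A label with a single replicate reports sd 0
#'   with a warning.
#' @export
aggregate_cpm <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("label", "replicate", "run", "hit_count", "library_size")
  if (!all(need %in% names(samples))) {
    stop("samples needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(samples) == 0) stop("samples must be non-empty")
  samples$label <- as.character(samples$label)
  samples$replicate <- as.character(samples$replicate)
  samples$cpm <- cpm(samples$hit_count, samples$library_size)
  rep_means <- stats::aggregate(cpm ~ label + replicate, data = samples,
                                FUN = mean)
  out <- lapply(split(rep_means$cpm, rep_means$label), function(r) {
    s <- if (length(r) < 2) {
      warning("single replicate: sample sd reported as 0")
      0
    } else {
      sd(r)
    }
    c(mean_cpm = mean(r), sd_cpm = s, n_replicates = length(r))
  })
  stats <- do.call(rbind, out)
  tibble(label = rownames(stats),
         mean_cpm = unname(stats[, "mean_cpm"]),
         sd_cpm = unname(stats[, "sd_cpm"]),
         n_replicates = as.integer(unname(stats[, "n_replicates"])))
}
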