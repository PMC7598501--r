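#' ChIP-seq mapper configuration
#'
#' @param n_sampled_reads Reads analyzed per library (ChIP and input are
#'   sampled to the same size; default one million).
#' @param bit_score_threshold Minimum local-alignment bit score for a
#'   hit.  90 is the middle of the commonly tested 30/90/150 ladder.
#' @param top_n_clusters Number of leading clusters used as the mapping
#'   reference (default 1000).
#' @param k,min_shared_kmers,max_candidates Candidate prefilter: k-mer
#'   size, minimum shared canonical k-mers, and the per-read candidate
#'   cap (0 = exhaustive).
#' @param precedence Which selection criterion claims clusters
#'   satisfying both; see [select_candidates()].
#' @param scoring An [alignment_scoring()] list.
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(n_sampled_reads = 1e6L,
                          bit_score_threshold = 90,
                          top_n_clusters = 1000L, k = 10L,
                          min_shared_kmers = 2L, max_candidates = 32L,
                          precedence = c("high_abundance", "enriched"),
                          scoring = alignment_scoring()) {
  precedence <- match.arg(precedence)
  if (n_sampled_reads <= 0) stop("n_sampled_reads must be > 0")
  if (top_n_clusters < 1) stop("top_n_clusters must be >= 1")
  structure(
    list(n_sampled_reads = as.integer(n_sampled_reads),
         bit_score_threshold = bit_score_threshold,
         top_n_clusters = as.integer(top_n_clusters), k = as.integer(k),
         min_shared_kmers = as.integer(min_shared_kmers),
         max_candidates = as.integer(max_candidates),
         precedence = precedence, scoring = scoring),
    class = "mapper_config")
}

#' Map reads onto cluster references
#'
#' Performs a similarity search of each read (both orientations) against
#' the member reads of the leading clusters.  A read contributes at most
#' one hit: to the cluster containing its best-scoring member match with
#' bit score at or above the threshold, ties going to the lower-ranked
#' (more abundant) cluster.  Reads with no qualifying match contribute
#' nothing, so total hits never exceed the library size.
#'
#' @param reads A [read_set()] of reads to map (ChIP or input library).
#' @param clusters Cluster tibble from [cluster_reads()].
#' @param rs The WGS [read_set()] holding cluster member sequences.
#' @param cfg A [mapper_config()].
#' @return Named integer vector of hit counts, one per analyzed cluster
#'   (zeros included), in cluster rank order.
#' @export
map_reads_to_clusters <- function(reads, clusters, rs, cfg = mapper_config()) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(clusters) == 0) stop("invalid argument: empty cluster list")
  top <- clusters[seq_len(min(cfg$top_n_clusters, nrow(clusters))), ]
  ref_ids <- unlist(top$members)
  ref_rank <- rep(seq_len(nrow(top)), lengths(top$members))
  ref_seq <- rs$seq[match(ref_ids, rs$id)]
  if (anyNA(ref_seq)) stop("cluster members missing from the WGS read set")
  hits <- setNames(integer(nrow(top)), top$cluster_id)
  if (nrow(reads) == 0) return(hits)
  cand <- kmer_candidates_cpp(reads$seq, ref_seq, cfg$k,
                              cfg$min_shared_kmers, cfg$max_candidates)
  if (length(cand$query) == 0) return(hits)
  score <- sw_scores_cpp(reads$seq, ref_seq, cand$query, cand$ref,
                         cand$strand, cfg$scoring$match,
                         cfg$scoring$mismatch, cfg$scoring$gap)
  bits <- alignment_bit_score(score, cfg$scoring)
  ok <- bits >= cfg$bit_score_threshold
  if (!any(ok)) return(hits)
  q <- cand$query[ok]
  rk <- ref_rank[cand$ref[ok]]
  s <- score[ok]
  # best score per read; ties to the lowest cluster rank
  ord <- order(q, -s, rk)
  first <- !duplicated(q[ord])
  assigned <- rk[ord][first]
  tab <- table(factor(assigned, levels = seq_len(nrow(top))))
  hits[] <- as.integer(tab)
  hits
}

#' Per-cluster ChIP/input enrichment records
#'
#' Ratio of ChIP to input hits per cluster, for equally sized ChIP and
#' input libraries.  Clusters with zero input hits get an undefined
#' (NA) ratio and are excluded from means; a zero ChIP count over
#' positive input gives ratio 0.
#'
#' @param chip_hits,input_hits Named hit-count vectors over the same
#'   clusters, e.g. from [map_reads_to_clusters()].
#' @param cfg A [mapper_config()].
#' @param scale_by_library_size Allow unequal library sizes by dividing
#'   each count by its library total before taking the ratio.  Off by
#'   default: the standard design samples both libraries to the same
#'   size, and unequal inputs without this flag are refused.
#' @param chip_total,input_total Library sizes, needed only when
#'   scaling.
#' @return An `enrichment_records` tibble: `cluster_id`, `chip_hits`,
#'   `input_hits`, `ratio`, ordered by cluster rank.
#' @export
compute_enrichment <- function(chip_hits, input_hits, cfg = mapper_config(),
                               scale_by_library_size = FALSE,
                               chip_total = NULL, input_total = NULL) {
  if (!identical(names(chip_hits), names(input_hits))) {
    stop("chip and input hit maps must cover the same clusters")
  }
  if (scale_by_library_size) {
    if (is.null(chip_total) || is.null(input_total)) {
      stop("library totals are required when scaling by library size")
    }
    ratio_num <- chip_hits / chip_total
    ratio_den <- input_hits / input_total
  } else {
    if (!is.null(chip_total) && !is.null(input_total) &&
        chip_total != input_total) {
      stop("unequal library sizes; resample to equal sizes or set ",
           "scale_by_library_size = TRUE")
    }
    ratio_num <- chip_hits
    ratio_den <- input_hits
  }
  ratio <- ifelse(input_hits > 0, ratio_num / ratio_den, NA_real_)
  out <- tibble(cluster_id = names(chip_hits),
                chip_hits = as.integer(chip_hits),
                input_hits = as.integer(input_hits),
                ratio = as.numeric(ratio))
  class(out) <- c("enrichment_records", class(tibble()))
  out
}

#' Mean ChIP/input enrichment over analyzed clusters
#'
#' Arithmetic mean of the defined per-cluster ratios; undefined ratios
#' (zero input hits) are excluded.
#'
#' @param records An `enrichment_records` tibble.
#' @return Numeric mean ratio.
#' @export
mean_enrichment <- function(records) {
  r <- records$ratio[!is.na(records$ratio)]
  if (length(r) == 0) stop("undefined mean: no cluster has a defined ratio")
  mean(r)
}

#' Candidate-selection hit thresholds
#'
#' The dual criteria express their support thresholds as fractions of
#' the analyzed reads: enriched candidates need at least 0.01% of ChIP
#' hits and high-abundance candidates more than 1%.  For one million
#' analyzed reads these are 100 and 10,000 hits.
#'
#' @param n_sampled_reads Analyzed reads per library.
#' @return List with `enriched_min_hits` (inclusive bound) and
#'   `high_abundance_min_hits` (exclusive bound).
#' @export
selection_thresholds <- function(n_sampled_reads) {
  list(enriched_min_hits = 1e-4 * n_sampled_reads,
       high_abundance_min_hits = 0.01 * n_sampled_reads)
}

#' Select centromere-candidate clusters
#'
#' Applies the dual criteria: *high-abundance* clusters have ratio > 1
#' and ChIP hits above 1% of the analyzed reads; *enriched* clusters
#' have ratio > 2 supported by at least 0.01% of ChIP hits.  Ratio
#' bounds are strict (a ratio of exactly 2 is not enriched).  The groups
#' are disjoint: clusters satisfying both are assigned by `precedence`
#' (default the high-abundance block first, matching how published
#' selections tabulate such clusters).
#'
#' @param records An `enrichment_records` tibble.
#' @param cfg A [mapper_config()]; supplies `n_sampled_reads` and
#'   `precedence`.
#' @return List of two tibbles, `high_abundance` and `enriched`, each
#'   sorted by cluster rank.
#' @export
select_candidates <- function(records, cfg = mapper_config()) {
  th <- selection_thresholds(cfg$n_sampled_reads)
  ratio <- ifelse(is.na(records$ratio), -Inf, records$ratio)
  high <- ratio > 1 & records$chip_hits > th$high_abundance_min_hits
  enr <- ratio > 2 & records$chip_hits >= th$enriched_min_hits
  if (cfg$precedence == "high_abundance") {
    enr <- enr & !high
  } else {
    high <- high & !enr
  }
  list(high_abundance = records[high, ], enriched = records[enr, ])
}

#' Enrichment report table
#'
#' One row per selected cluster, grouped by selection criterion, with
#' hit counts, the ChIP/input ratio rounded half-up to two decimals, and
#' the cluster annotation when available.
#'
#' @param records An `enrichment_records` tibble.
#' @param cfg A [mapper_config()].
#' @param annotations Optional named character vector of cluster
#'   annotations (`cluster_id` -> repeat type).
#' @return Tibble with columns `criteria`, `cluster`, `chip_hits`,
#'   `input_hits`, `ratio`, `annotation`.
#' @export
enrichment_report <- function(records, cfg = mapper_config(),
                              annotations = NULL) {
  sel <- select_candidates(records, cfg)
  blocks <- list(
    high_abundance = sel$high_abundance,
    enriched = sel$enriched)
  rows <- lapply(names(blocks), function(b) {
    x <- blocks[[b]]
    if (nrow(x) == 0) return(NULL)
    tibble(criteria = b, cluster = x$cluster_id,
           chip_hits = x$chip_hits, input_hits = x$input_hits,
           ratio = round_half_up(x$ratio, 2),
           annotation = if (is.null(annotations)) NA_character_ else
             unname(annotations[x$cluster_id]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble(criteria = character(), cluster = character(),
                  chip_hits = integer(), input_hits = integer(),
                  ratio = numeric(), annotation = character())
  }
  out
}

#' Published cCENH3 cluster hit counts
#'
#' The 28 repeat clusters selected as CenH3-centromere candidates in a
#' published *Tribolium castaneum* cCENH3 ChIP-seq mapping experiment
#' (one million ChIP and one million input reads mapped onto the top
#' 1000 WGS repeat clusters), shipped as a plain-text fixture.  The
#' `ratio_printed` column is the ratio as published (two decimals);
#' `criteria` records which selection block each cluster was tabulated
#' under.
#'
#' @return Tibble with `criteria`, `cluster`, `chip_hits`, `input_hits`,
#'   `ratio_printed`, `repeat_type`.
#' @export
cench3_cluster_hits <- function() {
  path <- system.file("extdata", "cench3_cluster_hits.tsv",
                      package = "centroscope", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
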