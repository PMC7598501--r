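#' Build a read similarity graph
#'
#' The graph contains an undirected edge for every read pair whose best
#' local alignment, in either orientation, reaches `min_identity`
#' (matches / alignment columns) over at least `min_overlap` of the read
#' length.  The contract is defined by the exhaustive all-vs-all
#' comparison; by default a canonical k-mer prefilter proposes candidate
#' pairs so that desk-scale sets stay fast, and tests verify equivalence
#' against brute force on small sets.
#'
#' Default thresholds (identity 0.90 over 0.55 of the read length)
#' follow the convention of graph-based repeat-clustering pipelines for
#' low-pass reads.
#'
#' @param rs A [read_set()] of uniform-length reads.
#' @param min_identity Minimum alignment identity in `[0, 1]`.
#' @param min_overlap Minimum aligned fraction of the read length.
#' @param k Prefilter k-mer size.
#' @param min_shared_kmers Candidate pairs must share at least this many
#'   canonical k-mers.
#' @param exhaustive Align all pairs instead of prefiltered candidates.
#' @param scoring Alignment scoring: match, mismatch, gap (linear).
#' @return Tibble of edges: `read_a`, `read_b`, `identity`,
#'   `overlap_fraction`, `orientation`.
#' @export
build_similarity_graph <- function(rs, min_identity = 0.90,
                                   min_overlap = 0.55, k = 10L,
                                   min_shared_kmers = 1L,
                                   exhaustive = FALSE,
                                   scoring = alignment_scoring()) {
  stopifnot(inherits(rs, "read_set"))
  empty <- tibble(read_a = character(), read_b = character(),
                  identity = numeric(), overlap_fraction = numeric(),
                  orientation = character())
  if (nrow(rs) < 2) return(empty)
  len <- read_length(rs)
  pairs <- if (exhaustive) {
    t(utils::combn(nrow(rs), 2))
  } else {
    kmer_pairs_cpp(rs$seq, as.integer(k), as.integer(min_shared_kmers))
  }
  if (nrow(pairs) == 0) return(empty)
  st <- sw_pairs_cpp(rs$seq, pairs, scoring$match, scoring$mismatch,
                     scoring$gap)
  identity <- ifelse(st$columns > 0, st$matches / st$columns, 0)
  overlap <- pmin(1, st$columns / len)
  keep <- identity >= min_identity & overlap >= min_overlap
  tibble(read_a = rs$id[pairs[keep, 1]], read_b = rs$id[pairs[keep, 2]],
         identity = identity[keep], overlap_fraction = overlap[keep],
         orientation = as.character(st$orientation[keep]))
}

#' Alignment scoring scheme
#'
#' Match/mismatch/linear-gap scores used throughout the package, plus
#' the Karlin-Altschul parameters used to express raw scores in bits.
#'
#' @param match,mismatch,gap Integer scores (gap is linear per column).
#' @param lambda,K Karlin-Altschul parameters for the bit-score
#'   conversion (defaults are the ungapped values for +1/-2 scoring).
#' @return A list of scoring parameters.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -2L, gap = -3L,
                              lambda = 1.28, K = 0.46) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap), lambda = lambda, K = K)
}

#' Bit score of a raw local-alignment score
#'
#' `(lambda * S - ln K) / ln 2`, the normalized score scale used for
#' similarity-search hit thresholds.
#'
#' @param score Raw alignment score(s).
#' @param scoring An [alignment_scoring()] list.
#' @return Numeric bit score(s).
#' @export
alignment_bit_score <- function(score, scoring = alignment_scoring()) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

#' Cluster reads from a similarity graph
#'
#' Repeat clusters are the connected components with at least
#' `min_cluster_size` members of the similarity graph; all other reads
#' are singletons.  Clusters are ranked CL1, CL2, ... by descending
#' member count (ties broken by the lexicographically smallest member
#' identifier), so cluster order reflects genome abundance.
#'
#' @param edges Edge tibble from [build_similarity_graph()].
#' @param rs The [read_set()] the edges were built over.
#' @param min_cluster_size Minimum component size to call a cluster.
#' @return List with `clusters` (tibble: `cluster_id`, `size`,
#'   `genome_proportion`, `members` list-column) and `summary`
#'   (a [clustering_summary()]).
#' @export
cluster_reads <- function(edges, rs, min_cluster_size = 2L) {
  stopifnot(inherits(rs, "read_set"))
  g <- igraph::graph_from_data_frame(
    edges[, c("read_a", "read_b")], directed = FALSE,
    vertices = data.frame(name = rs$id))
  comp <- igraph::components(g)
  members <- split(rs$id, comp$membership)
  members <- members[lengths(members) >= min_cluster_size]
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  total <- nrow(rs)
  clustered <- sum(lengths(members))
  clusters <- tibble(
    cluster_id = paste0("CL", seq_along(members)),
    size = unname(lengths(members)),
    genome_proportion = unname(lengths(members)) / total,
    members = unname(members))
  list(clusters = clusters,
       summary = clustering_summary(total, clustered, nrow(clusters)))
}

#' Clustering census summary
#'
#' Read accounting of a clustering run: clustered plus singleton reads
#' partition the analyzed total, and the clustered fraction is their
#' ratio.
#'
#' @param total_reads Total analyzed reads.
#' @param clustered_reads Reads assigned to clusters.
#' @param n_clusters Number of clusters.
#' @return A `clustering_summary` list with fields `total_reads`,
#'   `clustered_reads`, `singleton_reads`, `n_clusters`,
#'   `clustered_fraction`.
#' @export
clustering_summary <- function(total_reads, clustered_reads, n_clusters) {
  stopifnot(clustered_reads <= total_reads)
  structure(
    list(total_reads = as.integer(total_reads),
         clustered_reads = as.integer(clustered_reads),
         singleton_reads = as.integer(total_reads - clustered_reads),
         n_clusters = as.integer(n_clusters),
         clustered_fraction = clustered_reads / total_reads),
    class = "clustering_summary")
}

#' @export
print.clustering_summary <- function(x, ...) {
  cat(sprintf(
    "<clustering_summary> %d reads: %d clustered (%.2f%%) in %d clusters, %d singletons\n",
    x$total_reads, x$clustered_reads, 100 * x$clustered_fraction,
    x$n_clusters, x$singleton_reads))
  invisible(x)
}

#' Genome proportion of a cluster
#'
#' A cluster's share of the analyzed reads estimates its genome
#' proportion (low-pass reads sample the genome uniformly).
#'
#' @param cluster A cluster row (with `size`), a member-id vector, or a
#'   member count.
#' @param total_reads Total analyzed reads (> 0, >= member count).
#' @return Numeric proportion in `[0, 1]`.
#' @export
genome_proportion <- function(cluster, total_reads) {
  n <- if (is.numeric(cluster)) {
    cluster
  } else if (is.character(cluster)) {
    length(cluster)
  } else if (is.list(cluster) && !is.null(cluster$size)) {
    cluster$size
  } else {
    stop("cannot interpret cluster argument")
  }
  if (total_reads <= 0) stop("invalid argument: total_reads must be > 0")
  if (any(n < 1) || any(n > total_reads)) {
    stop("member count must satisfy 0 < count <= total_reads")
  }
  n / total_reads
}

#' Annotate a cluster against a repeat library
#'
#' Each member read is aligned against every library sequence; the
#' cluster label is the library sequence receiving the plurality of
#' member best hits at `min_identity` or better.  When fewer than half
#' of the members hit anything the cluster is labeled `"unknown"`.
#'
#' @param members Character vector of member read identifiers.
#' @param rs The [read_set()] holding the member sequences.
#' @param library Named character vector of reference sequences.
#' @param min_identity Minimum alignment identity for a hit.
#' @param min_overlap Minimum aligned fraction of the shorter of read
#'   and reference.
#' @param scoring An [alignment_scoring()] list.
#' @return A single label or `"unknown"`.
#' @export
annotate_cluster <- function(members, rs, library, min_identity = 0.80,
                             min_overlap = 0.5,
                             scoring = alignment_scoring()) {
  if (length(library) == 0) stop("library must be non-empty")
  if (is.null(names(library))) stop("library must be named")
  hits <- member_best_hits(members, rs, library, scoring)
  minlen <- pmin(nchar(rs$seq[match(members, rs$id)])[hits$member],
                 nchar(library)[hits$ref])
  ok <- hits$identity >= min_identity & hits$columns >= min_overlap * minlen
  if (sum(ok) < length(members) / 2) return("unknown")
  tab <- table(names(library)[hits$ref[ok]])
  names(tab)[order(-tab, names(tab))][1]
}

#' Subfamily proportions within a cluster
#'
#' Assigns each member read to the subfamily consensus with the
#' highest-scoring local alignment (ties broken to the lexicographically
#' first label); reads whose best identity falls below `min_identity`
#' count as unassigned.  Proportions are assigned counts over cluster
#' size.
#'
#' @param members Character vector of member read identifiers.
#' @param rs The [read_set()] holding the member sequences.
#' @param consensuses Named character vector of subfamily consensus
#'   sequences.
#' @param min_identity Minimum identity for assignment.
#' @param scoring An [alignment_scoring()] list.
#' @return A `subfamily_profile`: list with `proportions` (named
#'   numeric) and `unassigned_fraction`; the two sum to 1.
#' @export
subfamily_proportions <- function(members, rs, consensuses,
                                  min_identity = 0.70,
                                  scoring = alignment_scoring()) {
  if (length(consensuses) == 0) stop("consensuses must be non-empty")
  if (length(members) == 0) stop("cluster must be non-empty")
  labels <- sort(names(consensuses))
  consensuses <- consensuses[labels]
  hits <- member_best_hits(members, rs, consensuses, scoring)
  assigned <- rep(NA_character_, length(members))
  ok <- hits$identity >= min_identity
  assigned[hits$member[ok]] <- labels[hits$ref[ok]]
  counts <- table(factor(assigned, levels = labels))
  structure(
    list(proportions = setNames(as.numeric(counts) / length(members),
                                labels),
         unassigned_fraction = mean(is.na(assigned))),
    class = "subfamily_profile")
}

# best reference hit per member read: aligns every member against every
# reference (small reference sets, so brute force), ties to the first
# (lexicographically ordered upstream) reference
member_best_hits <- function(members, rs, refs, scoring) {
  idx <- match(members, rs$id)
  if (anyNA(idx)) stop("member identifiers missing from read set")
  seqs <- c(rs$seq[idx], unname(refs))
  nm <- length(members)
  pairs <- cbind(rep(seq_len(nm), each = length(refs)),
                 nm + rep(seq_along(refs), nm))
  st <- sw_pairs_cpp(seqs, pairs, scoring$match, scoring$mismatch,
                     scoring$gap)
  score <- matrix(st$score, nrow = length(refs))
  ident <- matrix(ifelse(st$columns > 0, st$matches / st$columns, 0),
                  nrow = length(refs))
  cols <- matrix(st$columns, nrow = length(refs))
  best <- apply(score, 2, which.max)
  list(member = seq_len(nm), ref = best,
       identity = ident[cbind(best, seq_len(nm))],
       columns = cols[cbind(best, seq_len(nm))],
       score = score[cbind(best, seq_len(nm))])
}
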