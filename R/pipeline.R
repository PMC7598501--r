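#' Pipeline configuration
#'
#' One flat configuration drives the whole analysis: simulate a
#' synthetic repeatome, preprocess and subsample the WGS reads, cluster
#' them, map ChIP and input libraries onto the clusters, and select
#' centromere-candidate clusters.  Every stage parameter has a default;
#' a configuration round-trips unchanged through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed Global seed; per-stage seeds follow [derive_seed()].
#' @param genome_length,n_chromosomes,centromere_fraction Genome shape
#'   (see [genome_spec()]).
#' @param coverage Target clustering coverage (reads are simulated at
#'   1.5x this and randomly subsampled down, mirroring a preprocessing
#'   chain that scales a larger run down).
#' @param read_length Read length in nt.
#' @param quality_cutoff,pass_fraction Quality-filter parameters.
#' @param chip_weight,background_weight,occupied_fraction Occupancy
#'   model for the centromeric major satellite
#'   (see [occupancy_model()]).
#' @param n_chip_reads Reads per ChIP/input library.
#' @param min_identity,min_overlap Similarity-graph thresholds.
#' @param bit_score_threshold,top_n_clusters Mapper parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, genome_length = 2e6L,
                            n_chromosomes = 2L,
                            centromere_fraction = 0.435, coverage = 0.2,
                            read_length = 151L, quality_cutoff = 10L,
                            pass_fraction = 0.95, chip_weight = 4,
                            background_weight = 1,
                            occupied_fraction = 0.5,
                            n_chip_reads = 20000L, min_identity = 0.90,
                            min_overlap = 0.55,
                            bit_score_threshold = 90,
                            top_n_clusters = 1000L) {
  structure(
    list(seed = as.integer(seed),
         genome_length = as.integer(genome_length),
         n_chromosomes = as.integer(n_chromosomes),
         centromere_fraction = centromere_fraction, coverage = coverage,
         read_length = as.integer(read_length),
         quality_cutoff = as.integer(quality_cutoff),
         pass_fraction = pass_fraction, chip_weight = chip_weight,
         background_weight = background_weight,
         occupied_fraction = occupied_fraction,
         n_chip_reads = as.integer(n_chip_reads),
         min_identity = min_identity, min_overlap = min_overlap,
         bit_score_threshold = bit_score_threshold,
         top_n_clusters = as.integer(top_n_clusters)),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the centromere-profiling pipeline end to end
#'
#' Executes simulate -> preprocess -> cluster -> map -> select ->
#' report on a synthetic repeatome, keeping ground truth at every stage.
#' The ChIP occupancy model puts `chip_weight` on the occupied fraction
#' of the centromeric major-satellite arrays, so the expected outcome is
#' that major-satellite clusters are selected as centromere candidates
#' while non-centromeric satellites fall below the selection criteria.
#'
#' With an `out_dir`, per-stage artifacts are persisted (genome FASTA,
#' annotation and centromere BED, read FASTQ, cluster and report TSV)
#' together with a YAML run manifest holding the configuration snapshot,
#' derived seeds and MD5 checksums; rerunning the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts and the
#'   manifest.
#' @return List with `genome`, `wgs` (preprocessed reads), `clustering`,
#'   `chip`/`input` read sets, `records` (enrichment), `selection`,
#'   `report`, `annotations` (cluster labels) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gspec <- genome_spec(config$genome_length,
                       families = tribolium_like_families(),
                       n_chromosomes = config$n_chromosomes,
                       centromere_fraction = config$centromere_fraction,
                       seed = derive_seed(config$seed, "genome"))
  genome <- build_genome(gspec)

  raw <- simulate_wgs_reads(genome, coverage = 1.5 * config$coverage,
                            read_length = config$read_length,
                            paired = TRUE,
                            seed = derive_seed(config$seed, "wgs"))
  pre <- quality_filter(raw, config$quality_cutoff, config$pass_fraction)
  pre <- trim_to_length(pre, config$read_length)
  pre <- interlace_pairs(pre)
  wgs <- subsample_to_coverage(pre, genome_length(genome),
                               config$coverage, config$read_length,
                               seed = derive_seed(config$seed, "subsample"))

  edges <- build_similarity_graph(wgs, config$min_identity,
                                  config$min_overlap)
  clustering <- cluster_reads(edges, wgs)

  model <- occupancy_model(
    weights = c(major_sat = config$chip_weight),
    background_weight = config$background_weight,
    occupied_fraction = config$occupied_fraction)
  libs <- simulate_chip_input(genome, model, config$n_chip_reads,
                              config$read_length,
                              seed = derive_seed(config$seed, "chip"))

  cfg <- mapper_config(n_sampled_reads = config$n_chip_reads,
                       bit_score_threshold = config$bit_score_threshold,
                       top_n_clusters = config$top_n_clusters)
  chip_hits <- map_reads_to_clusters(libs$chip, clustering$clusters, wgs,
                                     cfg)
  input_hits <- map_reads_to_clusters(libs$input, clustering$clusters,
                                      wgs, cfg)
  records <- compute_enrichment(chip_hits, input_hits, cfg)
  selection <- select_candidates(records, cfg)

  # annotate the selected clusters against the planted family library
  selected_ids <- c(selection$high_abundance$cluster_id,
                    selection$enriched$cluster_id)
  lib <- unlist(lapply(names(genome$library), function(f) {
    setNames(genome$library[[f]], rep(f, length(genome$library[[f]])))
  }))
  annotations <- vapply(selected_ids, function(cid) {
    m <- clustering$clusters$members[[
      match(cid, clustering$clusters$cluster_id)]]
    annotate_cluster(m, wgs, lib)
  }, character(1))
  report <- enrichment_report(records, cfg, annotations)

  manifest <- list(
    config = unclass(config),
    stage_seeds = setNames(
      lapply(pipeline_stages(), derive_seed, seed = config$seed),
      pipeline_stages()),
    version = as.character(utils::packageVersion("centroscope")),
    checksums = list())

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      genome = write_fasta(genome$sequences,
                           file.path(out_dir, "genome.fasta")),
      annotations = write_bed(genome$annotations,
                              file.path(out_dir, "annotations.bed")),
      centromeres = write_bed(genome$centromeres,
                              file.path(out_dir, "centromeres.bed")),
      wgs = write_fastq(wgs, file.path(out_dir, "wgs.fastq")),
      chip = write_fastq(libs$chip, file.path(out_dir, "chip.fastq")),
      input = write_fastq(libs$input, file.path(out_dir, "input.fastq")),
      clusters = write_cluster_summary(
        clustering$clusters, file.path(out_dir, "clusters.tsv")))
    rp <- file.path(out_dir, "report.tsv")
    write.table(as.data.frame(report), rp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, report = rp)
    manifest$checksums <- setNames(
      as.list(unname(tools::md5sum(unname(paths)))), names(paths))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  list(genome = genome, wgs = wgs, clustering = clustering,
       chip = libs$chip, input = libs$input, records = records,
       selection = selection, report = report,
       annotations = annotations, manifest = manifest)
}
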