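#' Pipeline configuration
#'
#' Bundles the inputs and stage settings of a full run.  When `vcf`,
#' `panel` and `manifest` paths are omitted, a synthetic cohort is generated
#' from `sim`; likewise `counts`/`sample_meta` default to simulated
#' expression data.
#'
#' @param outdir Output directory (created if absent).
#' @param vcf,panel,manifest,counts,sample_meta Optional input paths.
#' @param sim A [cohort_config()] for simulation (seed is overridden by
#'   `seed`).
#' @param screen A [screen_config()].
#' @param min_alt_reads Read-support filter threshold (default 4).
#' @param flank_bp Gene-region flank (default 500).
#' @param k Cluster count for the variety composition report (default 3,
#'   the granularity at which type-enriched groups are typically read off a
#'   variety dendrogram).
#' @param cpm_low_threshold,pseudocount Expression settings (defaults 10, 1).
#' @param aggregate `"tissue_mean"` (default) or `"per_sample"` heatmap
#'   columns.
#' @param seed Integer seed for all simulated stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            vcf = NULL, panel = NULL, manifest = NULL,
                            counts = NULL, sample_meta = NULL,
                            sim = cohort_config(),
                            screen = screen_config(),
                            min_alt_reads = 4, flank_bp = 500, k = 3,
                            cpm_low_threshold = 10, pseudocount = 1,
                            aggregate = c("tissue_mean", "per_sample"),
                            seed = 1L) {
  structure(list(outdir = outdir, vcf = vcf, panel = panel,
                 manifest = manifest, counts = counts,
                 sample_meta = sample_meta, sim = sim, screen = screen,
                 min_alt_reads = min_alt_reads, flank_bp = flank_bp, k = k,
                 cpm_low_threshold = cpm_low_threshold,
                 pseudocount = pseudocount,
                 aggregate = match.arg(aggregate),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the whole screen as one reproducible pipeline
#'
#' Orchestrates (simulate or load) -> support filter -> census -> association
#' screen -> variety clustering -> expression preprocessing, writing every
#' stage's table under `config$outdir` plus a machine-readable
#' `run_summary.json`.  Identical seeds give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run summary, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  if (is.null(config$vcf)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    table <- simulate_read_support(cohort, sim)
    manifest <- cohort$manifest
    panel <- cohort$panel
  } else {
    manifest <- read_manifest(config$manifest)
    panel <- read_panel(config$panel)
    table <- read_vcf(config$vcf, manifest)
  }

  supported <- filter_supported(table, config$min_alt_reads)
  cens <- census_polymorphisms(supported, panel, config$flank_bp)
  readr::write_tsv(cens, out("census.tsv"))
  readr::write_tsv(family_totals(cens), out("family_totals.tsv"))

  scr <- screen_associations(supported, manifest, panel,
                             config$screen, config$flank_bp)
  readr::write_tsv(scr$variants, out("screen_variants.tsv"))
  readr::write_tsv(scr$genes, out("screen_genes.tsv"))
  readr::write_tsv(fta_report(scr$genes), out("fta_report.tsv"))
  readr::write_tsv(scr$families, out("screen_families.tsv"))

  vaf <- compute_vaf(supported)
  d <- vaf_distance(vaf)
  write_matrix_tsv(d, out("vaf_distance.tsv"))
  write_matrix_tsv(similarity_from_distance(d), out("vaf_similarity.tsv"))
  tree <- ward_cluster(d)
  write_tree_newick(tree, out("variety_tree.nwk"))
  comp <- cluster_composition(tree, config$k, manifest)
  readr::write_tsv(comp, out("cluster_composition.tsv"))

  if (is.null(config$counts)) {
    expr <- simulate_expression(seed = config$seed)
    counts <- expr$counts
    sample_meta <- expr$sample_meta
    lib <- expr$library_sizes
  } else {
    counts <- read_counts(config$counts)
    sample_meta <- as_tibble(read.delim(config$sample_meta,
                                        colClasses = "character"))
    lib <- NULL
  }
  cpm <- cpm_normalize(counts, lib)
  low <- flag_low_expression(cpm, config$cpm_low_threshold)
  if (config$aggregate == "tissue_mean")
    cpm <- tissue_aggregate(cpm, sample_meta)
  hm <- log2_center(cpm[!low, , drop = FALSE], config$pseudocount)
  cl <- cluster_heatmap(hm, "both")
  write_matrix_tsv(cl$matrix, out("expression_heatmap.tsv"))
  write_tree_newick(cl$row_tree, out("expression_gene_tree.nwk"))
  write_tree_newick(cl$col_tree, out("expression_sample_tree.nwk"))

  summary <- list(
    seed = config$seed,
    n_genes_panel = nrow(panel),
    n_variants_raw = nrow(table),
    n_variants_supported = nrow(supported),
    n_variants_tested = sum(scr$variants$status == "ok"),
    n_fta_polymorphisms = sum(scr$variants$fta_class != "none"),
    n_fta_genes_strong = sum(scr$genes$n_fta_strong >= 1),
    n_fta_genes_very_strong = sum(scr$genes$n_fta_very_strong >= 1),
    family_fraction_with_fta = as.list(
      setNames(scr$families$fraction, scr$families$family)),
    composition_k = config$k,
    min_cluster_purity = min(comp$purity),
    n_genes_low_expression = sum(low),
    thresholds = list(min_alt_reads = config$min_alt_reads,
                      strong = config$screen$strong_threshold,
                      very_strong = config$screen$very_strong_threshold,
                      cpm_low = config$cpm_low_threshold))
  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# matrix with row/col names as a TSV with a leading id column
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
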