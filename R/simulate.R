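#' Configuration for the synthetic flax cohort
#'
#' The defaults emulate the study design the screen was built for: 79 fiber
#' flax and 112 linseed varieties, whole-genome sequencing at an effective
#' depth of about 7x, variants spread over the 424-gene candidate panel, and
#' near-homozygous genotypes (flax varieties are inbred lines of a largely
#' self-pollinating crop).
#'
#' @param n_fiber,n_linseed Group sizes (defaults 79 and 112).
#' @param panel Panel tibble giving gene regions to place variants in;
#'   defaults to the packaged 424-gene panel with its synthetic layout.
#' @param variants_per_gene Mean of the Poisson number of variants placed in
#'   each gene region (default 12, a desk-scale density that still yields
#'   thousands of variants panel-wide).
#' @param frac_associated_genes Fraction of genes designated as carrying
#'   type-associated variants (default 0.34, i.e. roughly a third of the
#'   panel).
#' @param delta Population alt-allele frequency difference between the two
#'   groups at associated variants, in `[0, 1]` (default 0.8).
#' @param base_freq Length-2 shape vector of the Beta distribution the null
#'   (and baseline associated) alt-allele frequencies are drawn from,
#'   rescaled into `[0.02, 0.98]` (default `c(0.8, 0.8)`, a U-shaped
#'   spectrum typical of polymorphic ascertained sites).
#' @param mean_depth Mean of the Poisson per-sample, per-site read depth
#'   (default 7).
#' @param base_error Per-read miscall probability (default 0.005).
#' @param inbreeding Probability that a genotype is drawn as fully
#'   homozygous (default 1: inbred lines; 0 gives Hardy-Weinberg draws).
#' @param frac_indel Fraction of simulated variants that are short indels
#'   rather than point substitutions (default 0.1).
#' @param seed Integer seed; every simulation is deterministic given it.
#' @return A config list of class `cohort_config`.
#' @export
cohort_config <- function(n_fiber = 79, n_linseed = 112,
                          panel = NULL,
                          variants_per_gene = 12,
                          frac_associated_genes = 0.34,
                          delta = 0.8,
                          base_freq = c(0.8, 0.8),
                          mean_depth = 7,
                          base_error = 0.005,
                          inbreeding = 1,
                          frac_indel = 0.1,
                          seed = 1L) {
  if (n_fiber < 2 || n_linseed < 2) abort("group sizes must be at least 2")
  if (delta < 0 || delta > 1) abort("delta must lie in [0, 1]")
  if (mean_depth <= 0) abort("mean_depth must be positive")
  if (frac_associated_genes < 0 || frac_associated_genes > 1)
    abort("frac_associated_genes must lie in [0, 1]")
  structure(list(n_fiber = n_fiber, n_linseed = n_linseed, panel = panel,
                 variants_per_gene = variants_per_gene,
                 frac_associated_genes = frac_associated_genes,
                 delta = delta, base_freq = base_freq,
                 mean_depth = mean_depth, base_error = base_error,
                 inbreeding = inbreeding, frac_indel = frac_indel,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Alt-allele frequency draw for null variants: Beta(base_freq) squeezed into
# [0.02, 0.98] so every simulated site is genuinely polymorphic.
draw_base_freq <- function(n, config) {
  0.02 + 0.96 * rbeta(n, config$base_freq[1], config$base_freq[2])
}

#' Simulate a two-group flax cohort with known truth
#'
#' Places variants in the panel's flanked gene regions, designates
#' `ceiling(frac_associated_genes * n_genes)` genes as associated (every
#' variant in them has `|p_fiber - p_linseed| = delta`, with the high-
#' frequency group chosen at random per variant), and draws latent diploid
#' genotypes per variety: with probability `inbreeding` a homozygote
#' (`2 * Bernoulli(p)` alt copies), otherwise a Hardy-Weinberg
#' `Binomial(2, p)` draw.
#'
#' @param config A [cohort_config()].
#' @return A list with `manifest` (sample tibble), `panel` (the panel used)
#'   and `truth`: a tibble with `variant_id`, `gene_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `is_associated`, `p_fiber`, `p_linseed`, and an integer
#'   matrix column `genotype` (alt copies, 0/1/2, one column per sample).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$delta > 1) abort("infeasible frequency difference: delta > 1")
  set.seed(config$seed)
  panel <- config$panel %||% flax_gene_panel()
  n_genes <- nrow(panel)

  manifest <- tibble(
    sample_id = c(sprintf("F%03d", seq_len(config$n_fiber)),
                  sprintf("L%03d", seq_len(config$n_linseed))),
    type_label = c(rep("fiber", config$n_fiber),
                   rep("linseed", config$n_linseed)),
    source = "synthetic")
  n_samples <- nrow(manifest)
  is_fiber <- manifest$type_label == "fiber"

  n_assoc_genes <- ceiling(config$frac_associated_genes * n_genes)
  assoc_genes <- if (n_assoc_genes > 0)
    sample(panel$gene_id, n_assoc_genes) else character()

  regions <- flanked_regions(panel)
  n_var_gene <- rpois(n_genes, config$variants_per_gene)
  bases <- c("A", "C", "G", "T")

  vars <- map_dfr(seq_len(n_genes), function(i) {
    k <- n_var_gene[i]
    if (k == 0) return(NULL)
    width <- regions$region_end[i] - regions$region_start[i]
    k <- min(k, width)
    pos <- sort(sample.int(width, k) - 1L) + regions$region_start[i]
    ref <- sample(bases, k, replace = TRUE)
    alt <- map_chr(ref, function(r) sample(setdiff(bases, r), 1))
    indel <- runif(k) < config$frac_indel
    alt[indel] <- paste0(ref[indel],
                         map_chr(seq_len(sum(indel)),
                                 function(.) paste(sample(bases, 2, replace = TRUE),
                                                   collapse = "")))
    tibble(gene_id = regions$gene_id[i], chrom = regions$chrom[i],
           pos = pos, ref = ref, alt = alt)
  })
  n_var <- nrow(vars)
  if (n_var == 0) abort("simulation produced no variants; raise variants_per_gene")

  is_assoc <- vars$gene_id %in% assoc_genes
  p_fiber <- p_linseed <- draw_base_freq(n_var, config)
  if (any(is_assoc)) {
    k <- sum(is_assoc)
    lo <- runif(k, 0, 1 - config$delta)
    fiber_high <- runif(k) < 0.5
    p_fiber[is_assoc] <- ifelse(fiber_high, lo + config$delta, lo)
    p_linseed[is_assoc] <- ifelse(fiber_high, lo, lo + config$delta)
  }

  genotype <- matrix(0L, n_var, n_samples,
                     dimnames = list(NULL, manifest$sample_id))
  for (j in seq_len(n_samples)) {
    p <- if (is_fiber[j]) p_fiber else p_linseed
    hom <- runif(n_var) < config$inbreeding
    g <- integer(n_var)
    g[hom] <- 2L * rbinom(sum(hom), 1L, p[hom])
    g[!hom] <- rbinom(sum(!hom), 2L, p[!hom])
    genotype[, j] <- g
  }

  truth <- vars |>
    mutate(variant_id = paste(.data$chrom, .data$pos + 1L, .data$ref,
                              .data$alt, sep = ":"),
           is_associated = is_assoc,
           p_fiber = p_fiber, p_linseed = p_linseed)
  truth$genotype <- genotype
  ord <- order(truth$chrom, truth$pos)
  truth <- truth[ord, ]
  list(manifest = manifest, panel = panel, truth = truth)
}

#' Simulate low-coverage read support for a cohort
#'
#' Per sample and site, total depth is `Poisson(mean_depth)` and the
#' alt-read count is `Binomial(depth, q)` with
#' `q = (g/2)(1 - base_error) + (1 - g/2) base_error`, `g` the latent
#' genotype.  Deterministic given the config seed.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param config The same [cohort_config()].
#' @return A variant table (see [read_vcf()]).
#' @export
simulate_read_support <- function(cohort, config = cohort_config()) {
  truth <- cohort$truth
  set.seed(config$seed + 1L)
  g <- truth$genotype
  n_var <- nrow(g); n_s <- ncol(g)
  dp <- matrix(rpois(n_var * n_s, config$mean_depth), n_var, n_s)
  q <- (g / 2) * (1 - config$base_error) + (1 - g / 2) * config$base_error
  ad <- matrix(rbinom(n_var * n_s, as.vector(dp), as.vector(q)), n_var, n_s)
  new_variant_table(chrom = truth$chrom, pos = truth$pos,
                    ref = truth$ref, alt = truth$alt,
                    ad = ad, dp = dp, samples = colnames(g))
}

#' Controlled vocabulary of flax tissue labels
#'
#' Seedling roots and shoots, leaves, flowers, stems and capsules, plus the
#' stem-dissection and seed tissues used in flax expression panels:
#' cortical parenchyma (`cPAR`), intrusively growing fibers (`iFIB`),
#' fibers depositing tertiary cell wall (`tFIB`), stem xylem (`sXYL`) and
#' embryo.
#'
#' @return Character vector of tissue labels.
#' @export
flax_tissues <- function() {
  c("root", "shoot", "leaf", "flower", "stem", "capsule",
    "cPAR", "iFIB", "tFIB", "sXYL", "embryo")
}

#' Simulate tissue-structured expression counts
#'
#' Gene baseline abundances are log-normal; a designated fraction of genes
#' are tissue markers whose mean is multiplied by `marker_fold` in one
#' tissue.  Counts are negative binomial around
#' `baseline_cpm / 1e6 * library_size`, with per-sample library sizes drawn
#' log-normally.
#'
#' @param n_genes Number of genes (default 400).
#' @param tissues Tissue labels (default [flax_tissues()]).
#' @param samples_per_tissue Replicates per tissue (default 3).
#' @param marker_fraction Fraction of genes made tissue markers (default 0.2).
#' @param marker_fold Fold-change of a marker gene in its tissue (default 50,
#'   the scale of a strong tissue marker).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param base_cpm_meanlog,base_cpm_sdlog Log-normal parameters of baseline
#'   CPM (defaults `log(20)` and 1.5, spanning silent to abundant genes).
#' @param lib_size_mean Mean library size in reads (default 2e6).
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `sample_meta` (tibble: `sample_id`, `tissue_label`, `variety`),
#'   `library_sizes` (named vector) and `truth` (tibble: `gene_id`,
#'   `is_marker`, `marker_tissue`, `base_cpm`).
#' @export
simulate_expression <- function(n_genes = 400, tissues = flax_tissues(),
                                samples_per_tissue = 3,
                                marker_fraction = 0.2, marker_fold = 50,
                                dispersion = 0.1,
                                base_cpm_meanlog = log(20),
                                base_cpm_sdlog = 1.5,
                                lib_size_mean = 2e6, seed = 1L) {
  if (length(tissues) < 2) abort("need at least 2 tissues")
  set.seed(as.integer(seed))
  n_s <- length(tissues) * samples_per_tissue
  sample_meta <- tibble(
    sample_id = sprintf("S%03d", seq_len(n_s)),
    tissue_label = rep(tissues, each = samples_per_tissue),
    variety = "synthetic")
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  base_cpm <- rlnorm(n_genes, base_cpm_meanlog, base_cpm_sdlog)
  is_marker <- runif(n_genes) < marker_fraction
  marker_tissue <- rep(NA_character_, n_genes)
  marker_tissue[is_marker] <- sample(tissues, sum(is_marker), replace = TRUE)
  lib <- round(rlnorm(n_s, log(lib_size_mean), 0.3))
  names(lib) <- sample_meta$sample_id

  mu <- outer(base_cpm, lib / 1e6)  # genes x samples expected counts
  for (i in which(is_marker)) {
    in_tissue <- sample_meta$tissue_label == marker_tissue[i]
    mu[i, in_tissue] <- mu[i, in_tissue] * marker_fold
  }
  counts <- matrix(rnbinom(n_genes * n_s, mu = as.vector(mu),
                           size = 1 / dispersion),
                   n_genes, n_s,
                   dimnames = list(gene_id, sample_meta$sample_id))
  list(counts = counts, sample_meta = sample_meta, library_sizes = lib,
       truth = tibble(gene_id = gene_id, is_marker = is_marker,
                      marker_tissue = marker_tissue, base_cpm = base_cpm))
}
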