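#' Screen configuration
#'
#' Thresholds and test settings for the flax type-association screen.
#' A polymorphism is called flax type-associated (FTA) when the Spearman
#' correlation between its per-variety VAF and the binary plant type reaches
#' `|r_s| >= strong_threshold` (0.4), and "very strong" at 0.6; the
#' classification is by the coefficient alone, with p- and q-values reported
#' alongside.
#'
#' @param strong_threshold,very_strong_threshold Inclusive `|r_s|` cutoffs
#'   (defaults 0.4 and 0.6).
#' @param type_coding Named numeric coding of the plant type used for
#'   correlations (default `c(linseed = 0, fiber = 1)`; FTA calls use
#'   `|r_s|`, so the coding only fixes the sign convention).
#' @param min_informative_samples Minimum samples with non-missing VAF for a
#'   variant to be tested (default 10).
#' @param mwu_exact_max_n Use the exact Mann-Whitney distribution when both
#'   group sizes are at most this (default 25) and the data are tie-free;
#'   otherwise the normal approximation with tie correction.
#' @param bh_scope `"panel"` (default) adjusts p-values across all tested
#'   variants; `"gene"` adjusts within each gene.
#' @return A config list of class `screen_config`.
#' @export
screen_config <- function(strong_threshold = 0.4, very_strong_threshold = 0.6,
                          type_coding = c(linseed = 0, fiber = 1),
                          min_informative_samples = 10,
                          mwu_exact_max_n = 25,
                          bh_scope = c("panel", "gene")) {
  if (!(strong_threshold > 0 && strong_threshold <= very_strong_threshold &&
        very_strong_threshold <= 1))
    abort("need 0 < strong_threshold <= very_strong_threshold <= 1")
  structure(list(strong_threshold = strong_threshold,
                 very_strong_threshold = very_strong_threshold,
                 type_coding = type_coding,
                 min_informative_samples = min_informative_samples,
                 mwu_exact_max_n = mwu_exact_max_n,
                 bh_scope = match.arg(bh_scope)),
            class = "screen_config")
}

#' Variant allele frequencies from depths
#'
#' `VAF = alt_depth / total_depth`, missing (`NA`) where the site has no
#' reads in a sample.
#'
#' @param table A variant table.
#' @return A tibble with `variant_id` and a numeric matrix column `vaf`
#'   (variants x samples).
#' @export
compute_vaf <- function(table) {
  vaf <- table$ad / table$dp
  vaf[table$dp == 0] <- NA_real_
  out <- tibble(variant_id = table$variant_id)
  out$vaf <- vaf
  out
}

# numeric 0/1 labels from a manifest under the config's type coding
type_labels <- function(manifest, config = screen_config()) {
  unname(config$type_coding[manifest$type_label])
}

#' Correlate one variant's VAF with the plant type
#'
#' Computes Spearman, Pearson and Kendall tau-b coefficients with p-values,
#' and the two-sided Mann-Whitney U test between the two groups, on the
#' pairwise-complete samples.  Variants with fewer informative samples than
#' `min_informative_samples`, or with only one class among them, are flagged
#' `untestable`; zero-variance VAF gives `undefined` (no test performed).
#'
#' @param vaf_row Numeric vector of per-sample VAF (may contain `NA`).
#' @param labels Numeric 0/1 type labels aligned with `vaf_row`.
#' @param config A [screen_config()].
#' @return A one-row tibble: `r_s`, `r_p`, `tau`, `p_s`, `p_p`, `p_tau`,
#'   `p_mwu`, `n_used`, `status` (`ok`, `untestable`, `undefined`).
#' @export
correlate_variant <- function(vaf_row, labels, config = screen_config()) {
  keep <- !is.na(vaf_row) & !is.na(labels)
  v <- vaf_row[keep]
  y <- labels[keep]
  nas <- tibble(r_s = NA_real_, r_p = NA_real_, tau = NA_real_,
                p_s = NA_real_, p_p = NA_real_, p_tau = NA_real_,
                p_mwu = NA_real_, n_used = length(v))
  if (length(v) < config$min_informative_samples || length(unique(y)) < 2)
    return(mutate(nas, status = "untestable"))
  if (stats::var(v) == 0)
    return(mutate(nas, status = "undefined"))

  sp <- suppressWarnings(cor.test(v, y, method = "spearman", exact = FALSE))
  pe <- cor.test(v, y, method = "pearson")
  ke <- suppressWarnings(cor.test(v, y, method = "kendall"))
  g1 <- v[y == 1]; g0 <- v[y == 0]
  ex <- length(g0) <= config$mwu_exact_max_n &&
    length(g1) <= config$mwu_exact_max_n
  mw <- suppressWarnings(wilcox.test(g1, g0, exact = ex))
  tibble(r_s = unname(sp$estimate), r_p = unname(pe$estimate),
         tau = unname(ke$estimate),
         p_s = sp$p.value, p_p = pe$p.value, p_tau = ke$p.value,
         p_mwu = mw$p.value, n_used = length(v), status = "ok")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and
#' mapped back to input order.  `NA` entries are passed through and do not
#' count towards `m`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return The adjusted values.
#' @export
adjust_bh <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Classify flax type-associated polymorphisms
#'
#' Inclusive thresholds on `|r_s|`: `very_strong` at 0.6, `strong` at 0.4,
#' otherwise (or for undefined coefficients) `none`.
#'
#' @param r_s Spearman coefficient(s); `NA` allowed.
#' @param config A [screen_config()].
#' @return Character vector in `{none, strong, very_strong}`.
#' @export
classify_fta <- function(r_s, config = screen_config()) {
  a <- abs(r_s)
  out <- rep("none", length(r_s))
  out[!is.na(a) & a >= config$strong_threshold] <- "strong"
  out[!is.na(a) & a >= config$very_strong_threshold] <- "very_strong"
  out
}

#' Run the VAF association screen
#'
#' The core analysis: per-variant VAF profiles are correlated with the
#' fiber/linseed label, p-values are BH-adjusted per statistic, variants are
#' classified as FTA by `|r_s|`, and results are summarized per gene and per
#' family.  Variants outside every panel region are dropped.
#'
#' @param table A (support-filtered) variant table.
#' @param manifest A manifest tibble matching the table's samples.
#' @param panel A panel tibble.
#' @param config A [screen_config()].
#' @param flank_bp Flank width for gene assignment (default 500).
#' @return An object of class `fta_screen`: a list with `variants` (one row
#'   per tested variant: coefficients, p- and q-values, `n_used`, `status`,
#'   `fta_class`, comma-joined `gene_ids`), `genes` ([summarize_genes()]),
#'   `families` ([summarize_families()]), `assignment` (gene/variant pairs)
#'   and `config`.
#' @export
screen_associations <- function(table, manifest, panel,
                                config = screen_config(), flank_bp = 500) {
  manifest <- validate_manifest(manifest)
  if (length(unique(manifest$type_label)) < 2)
    abort("association screen needs both fiber and linseed samples")
  stopifnot(identical(colnames(table$ad), manifest$sample_id))

  assignment <- assign_variants(table, panel, flank_bp)
  table <- table[table$variant_id %in% assignment$variant_id, ]
  vaf <- compute_vaf(table)
  labels <- type_labels(manifest, config)

  records <- map_dfr(seq_len(nrow(vaf)),
                     function(i) correlate_variant(vaf$vaf[i, ], labels, config))
  records <- bind_cols(tibble(variant_id = vaf$variant_id), records)

  gene_of <- assignment |>
    group_by(.data$variant_id) |>
    summarise(gene_ids = paste(sort(.data$gene_id), collapse = ","),
              .groups = "drop")
  records <- left_join(records, gene_of, by = "variant_id")

  adjust <- function(df) {
    mutate(df,
           q_s = adjust_bh(.data$p_s), q_p = adjust_bh(.data$p_p),
           q_tau = adjust_bh(.data$p_tau), q_mwu = adjust_bh(.data$p_mwu))
  }
  records <- if (config$bh_scope == "panel") {
    adjust(records)
  } else {
    records |> group_by(.data$gene_ids) |> adjust() |> ungroup()
  }
  records <- records |>
    mutate(fta_class = classify_fta(.data$r_s, config)) |>
    select("variant_id", "gene_ids", "r_s", "r_p", "tau",
           "p_s", "p_p", "p_tau", "p_mwu",
           "q_s", "q_p", "q_tau", "q_mwu",
           "n_used", "status", "fta_class")

  genes <- summarize_genes(records, panel, config)
  structure(list(variants = records,
                 genes = genes,
                 families = summarize_families(genes, panel),
                 assignment = assignment,
                 config = config),
            class = "fta_screen")
}

#' Per-gene FTA summary
#'
#' Counts each gene's FTA polymorphisms at both thresholds (`n_fta_strong`
#' counts `|r_s| >= 0.4`, so it includes the very strong ones) and the
#' maximum `|r_s|`.  Every panel gene is retained, with zeros; the reporting
#' convention of omitting FTA-free genes belongs to [fta_report()].
#'
#' @param records Per-variant screen records (the `variants` element of an
#'   `fta_screen`, or any tibble with `gene_ids`, `r_s`).
#' @param panel A panel tibble.
#' @param config A [screen_config()].
#' @return A tibble: `gene_id`, `family`, `n_fta_strong`,
#'   `n_fta_very_strong`, `max_abs_rs`.
#' @export
summarize_genes <- function(records, panel, config = screen_config()) {
  long <- records |>
    filter(!is.na(.data$gene_ids)) |>
    tidyr::separate_rows("gene_ids", sep = ",") |>
    rename(gene_id = "gene_ids")
  per_gene <- long |>
    group_by(.data$gene_id) |>
    summarise(
      n_fta_strong = sum(abs(.data$r_s) >= config$strong_threshold,
                         na.rm = TRUE),
      n_fta_very_strong = sum(abs(.data$r_s) >= config$very_strong_threshold,
                              na.rm = TRUE),
      max_abs_rs = if (all(is.na(.data$r_s))) NA_real_ else
        max(abs(.data$r_s), na.rm = TRUE),
      .groups = "drop")
  panel |>
    select("gene_id", "family") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(n_fta_strong = dplyr::coalesce(.data$n_fta_strong, 0L),
           n_fta_very_strong = dplyr::coalesce(.data$n_fta_very_strong, 0L))
}

#' Report table of genes with FTA polymorphisms
#'
#' The publication-style view: genes without any FTA polymorphism are
#' omitted.
#'
#' @param genes A gene summary tibble ([summarize_genes()]).
#' @return The rows with `n_fta_strong >= 1`, ordered by family and gene.
#' @export
fta_report <- function(genes) {
  genes |>
    filter(.data$n_fta_strong >= 1) |>
    arrange(.data$family, .data$gene_id)
}

#' Per-family FTA fractions
#'
#' For each gene family, the number and fraction of its genes carrying at
#' least one FTA polymorphism.
#'
#' @param genes A gene summary tibble ([summarize_genes()]).
#' @param panel A panel tibble (defines family sizes).
#' @return A tibble: `family`, `n_genes`, `n_genes_with_fta`, `fraction`
#'   (`NA` for an empty family).
#' @export
summarize_families <- function(genes, panel) {
  sizes <- panel |> count(.data$family, name = "n_genes")
  hits <- genes |>
    group_by(.data$family) |>
    summarise(n_genes_with_fta = sum(.data$n_fta_strong >= 1), .groups = "drop")
  sizes |>
    left_join(hits, by = "family") |>
    mutate(n_genes_with_fta = dplyr::coalesce(.data$n_genes_with_fta, 0L),
           fraction = ifelse(.data$n_genes > 0,
                             .data$n_genes_with_fta / .data$n_genes, NA_real_))
}

#' @exportS3Method generics::tidy
tidy.fta_screen <- function(x, ...) x$variants

#' @exportS3Method generics::glance
glance.fta_screen <- function(x, ...) {
  tibble(n_variants = nrow(x$variants),
         n_tested = sum(x$variants$status == "ok"),
         n_fta_strong = sum(x$variants$fta_class != "none"),
         n_fta_very_strong = sum(x$variants$fta_class == "very_strong"),
         n_genes = nrow(x$genes),
         n_genes_with_fta = sum(x$genes$n_fta_strong >= 1))
}

#' @export
print.fta_screen <- function(x, ...) {
  g <- glance(x)
  cat("<fta_screen>\n",
      " variants tested: ", g$n_tested, " of ", g$n_variants, "\n",
      " FTA polymorphisms (|r_s| >= ", x$config$strong_threshold, "): ",
      g$n_fta_strong, " (very strong >= ", x$config$very_strong_threshold,
      ": ", g$n_fta_very_strong, ")\n",
      " genes with FTA polymorphisms: ", g$n_genes_with_fta, " of ",
      g$n_genes, "\n", sep = "")
  invisible(x)
}
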