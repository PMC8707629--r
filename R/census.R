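#' Filter variants by read support
#'
#' Keeps the records whose alternate allele is supported by at least
#' `min_alt_reads` reads in at least one sample (i.e. the maximum per-sample
#' alt depth reaches the threshold), regardless of variant allele frequency.
#' The default of 4 reads is the support rule suited to cohorts sequenced at
#' low effective coverage (about 7x), where genotype calls are unreliable but
#' repeated alt-read support at a site is informative.
#'
#' @param table A variant table.
#' @param min_alt_reads Minimum alt-read support in the best sample
#'   (default 4); 0 keeps everything.
#' @return The filtered variant table.
#' @export
filter_supported <- function(table, min_alt_reads = 4) {
  if (nrow(table) == 0) return(table)
  best <- apply(table$ad, 1, max)
  table[best >= min_alt_reads, ]
}

#' Per-gene polymorphism census
#'
#' Counts the (already support-filtered) polymorphisms assigned to each
#' gene's flanked region and reports the density per kilobase of analyzed
#' region, whose length is gene length plus both flanks (`+ 1000` bp at the
#' default 500-bp flank).  A variant inside two genes' regions increments
#' both counts.
#'
#' @param table A support-filtered variant table.
#' @param panel A panel tibble.
#' @param flank_bp Flank width in bp (default 500).
#' @return A tibble with one row per panel gene: `gene_id`, `family`,
#'   `n_polymorphisms`, `region_length_bp`, `density_per_kb`.
#' @export
census_polymorphisms <- function(table, panel, flank_bp = 500) {
  hits <- assign_variants(table, panel, flank_bp)
  counts <- hits |> count(.data$gene_id, name = "n_polymorphisms")
  flanked_regions(panel, flank_bp) |>
    select("gene_id", "family", "region_length_bp") |>
    left_join(counts, by = "gene_id") |>
    mutate(n_polymorphisms = dplyr::coalesce(.data$n_polymorphisms, 0L),
           density_per_kb = .data$n_polymorphisms / (.data$region_length_bp / 1000)) |>
    select("gene_id", "family", "n_polymorphisms", "region_length_bp",
           "density_per_kb")
}

#' Per-family polymorphism totals
#'
#' @param census A census tibble ([census_polymorphisms()]).
#' @return A tibble `family`, `n_polymorphisms` summing the per-gene counts.
#' @export
family_totals <- function(census) {
  census |>
    group_by(.data$family) |>
    summarise(n_polymorphisms = sum(.data$n_polymorphisms), .groups = "drop")
}
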