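#' Read a gene panel from a BED-like file
#'
#' The panel format is BED6+1: `chrom`, `start`, `end`, `gene_id`, `family`,
#' `strand`, tab-separated, no header, `#` comment lines allowed.
#' Coordinates are taken as-is in the BED convention (0-based, half-open).
#'
#' @param path Path to the panel file.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene_id`,
#'   `family`, `strand`, one row per gene.
#' @examples
#' panel <- read_panel(flax_panel_file())
#' nrow(panel)    # 424 candidate genes
#' @export
read_panel <- function(path) {
  cols <- c("chrom", "start", "end", "gene_id", "family", "strand")
  raw <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               colClasses = c("character", "integer", "integer",
                              "character", "character", "character")),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    warn(paste0("panel file '", path, "' has no regions; returning an empty panel"))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), family = character(),
                  strand = character()))
  }
  if (ncol(raw) < 6)
    abort("panel file must have 6 columns: chrom, start, end, gene_id, family, strand")
  panel <- as_tibble(setNames(raw[, 1:6], cols))
  bad <- panel$end <= panel$start
  if (any(bad))
    abort(paste0("panel region with end <= start for gene '",
                 panel$gene_id[which(bad)[1]], "'"))
  dup <- panel$gene_id[duplicated(panel$gene_id)]
  if (length(dup) > 0)
    abort(paste0("duplicate gene_id in panel: ", paste(unique(dup), collapse = ", ")))
  panel$strand[!panel$strand %in% c("+", "-")] <- "unknown"
  panel
}

#' Path to the packaged 424-gene flax candidate panel
#'
#' The packaged panel carries the 424 candidate genes of the flax screen
#' (lignin, CTL, BGAL, ABC/HMA, lignan, TUB, CESA, RGL, fatty-acid and ACT
#' families) with their family tags.  The coordinates in the file are a
#' deterministic synthetic layout over 15 chromosomes intended for
#' simulation and testing; they are not genome positions.
#'
#' @return Path to the installed BED6+1 file.
#' @export
flax_panel_file <- function() {
  system.file("extdata", "flax_panel_synthetic.bed", package = "flaxfta",
              mustWork = TRUE)
}

#' Load the packaged flax candidate-gene panel
#'
#' @return A panel tibble (see [read_panel()]) with 424 genes.
#' @export
flax_gene_panel <- function() {
  read_panel(flax_panel_file())
}

#' Per-family gene counts of a panel
#'
#' @param panel A panel tibble.
#' @return A tibble with columns `family`, `n_genes`, plus one `total` row.
#' @examples
#' validate_panel(flax_gene_panel())
#' @export
validate_panel <- function(panel) {
  fam <- panel |>
    count(.data$family, name = "n_genes") |>
    arrange(dplyr::desc(.data$n_genes), .data$family)
  bind_rows(fam, tibble(family = "total", n_genes = nrow(panel)))
}

# Flanked analysis regions: gene body plus flank_bp on each side, clipped at 0.
# Returned in the panel's row order.
flanked_regions <- function(panel, flank_bp = 500) {
  stopifnot(flank_bp >= 0)
  panel |>
    mutate(region_start = pmax(.data$start - flank_bp, 0L),
           region_end = .data$end + flank_bp,
           region_length_bp = (.data$end - .data$start) + 2L * flank_bp)
}

#' Assign variants to gene regions
#'
#' A variant belongs to every gene whose flanked region (gene body plus
#' `flank_bp` on each side) contains its position, under the half-open
#' convention `pos in [start - flank_bp, end + flank_bp)`.  Overlapping
#' genes each receive the variant; variants falling in no region are
#' omitted.
#'
#' @param variants A variant table ([read_vcf()]) or any tibble with
#'   `variant_id`, `chrom`, `pos` (0-based).
#' @param panel A panel tibble.
#' @param flank_bp Flank width in bp added on each side (default 500).
#' @return A tibble with columns `gene_id`, `variant_id` (one row per
#'   assignment).
#' @export
assign_variants <- function(variants, panel, flank_bp = 500) {
  regions <- flanked_regions(panel, flank_bp)
  hits <- map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    keep <- variants$chrom == r$chrom &
      variants$pos >= r$region_start & variants$pos < r$region_end
    tibble(gene_id = r$gene_id, variant_id = variants$variant_id[keep])
  })
  hits
}
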