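# Small in-code fixtures shared across tests.

tiny_manifest <- function(n_fiber = 3, n_linseed = 3) {
  tibble::tibble(
    sample_id = c(sprintf("F%02d", seq_len(n_fiber)),
                  sprintf("L%02d", seq_len(n_linseed))),
    type_label = c(rep("fiber", n_fiber), rep("linseed", n_linseed)),
    source = "test")
}

tiny_panel <- function() {
  tibble::tibble(chrom = c("Lu1", "Lu1", "Lu2"),
                 start = c(1000L, 2300L, 500L),
                 end = c(2000L, 4000L, 1500L),
                 gene_id = c("gA", "gB", "gC"),
                 family = c("lignin", "lignin", "CTL"),
                 strand = c("+", "-", "+"))
}

# variant table straight from depth matrices
tiny_table <- function(ad, dp, pos, chrom = "Lu1", samples = NULL,
                       ref = NULL, alt = NULL) {
  n <- length(pos)
  samples <- samples %||% paste0("s", seq_len(ncol(ad)))
  flaxfta:::new_variant_table(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = ref %||% rep("A", n), alt = alt %||% rep("T", n),
    ad = ad, dp = dp, samples = samples)
}

write_tiny_vcf <- function(path, lines) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
               lines$header, lines$body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
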