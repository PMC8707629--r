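#' Read a sample manifest
#'
#' Tab-separated with a header row and columns `sample_id`, `type_label`
#' (`fiber` or `linseed`) and `source`.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with those three columns.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(read.delim(path, colClasses = "character"))
  validate_manifest(m)
}

validate_manifest <- function(manifest) {
  need <- c("sample_id", "type_label")
  if (!all(need %in% names(manifest)))
    abort("manifest needs columns sample_id and type_label")
  if (!"source" %in% names(manifest)) manifest$source <- NA_character_
  if (anyDuplicated(manifest$sample_id))
    abort("manifest sample_ids must be unique")
  bad <- setdiff(unique(manifest$type_label), c("fiber", "linseed"))
  if (length(bad) > 0)
    abort(paste0("unknown type_label: ", paste(bad, collapse = ", "),
                 " (expected fiber or linseed)"))
  manifest[, c("sample_id", "type_label", "source")]
}

# Construct a variant table: one row per (site, alt allele), depth matrices
# as matrix columns aligned with `samples`.
new_variant_table <- function(chrom, pos, ref, alt, ad, dp, samples) {
  stopifnot(ncol(ad) == length(samples), ncol(dp) == length(samples))
  colnames(ad) <- colnames(dp) <- samples
  chrom <- unname(chrom); ref <- unname(ref); alt <- unname(alt)
  kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1 &
                   ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T"),
                 "SNV", "indel")
  tab <- tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                kind = kind,
                variant_id = paste(chrom, pos + 1L, ref, alt, sep = ":"))
  tab$ad <- ad
  tab$dp <- dp
  ord <- order(tab$chrom, tab$pos)
  tab[ord, ]
}

#' Read per-sample allelic depths from a VCF
#'
#' Builds the in-memory variant table the screen works on.  Depths are read
#' from the `AD` FORMAT field when present, otherwise from `AO`/`RO`;
#' genotype calls are ignored, as the whole analysis is based on variant
#' allele frequencies.  Multiallelic sites are decomposed into one record
#' per alternate allele, all sharing the site total depth (sum of the `AD`
#' entries).  VCF 1-based positions are converted to the internal 0-based
#' convention.  Samples are reordered to the manifest order.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param manifest A manifest tibble ([read_manifest()]).
#' @return A variant table: tibble with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `kind` (`SNV`/`indel`), `variant_id`, and integer matrix
#'   columns `ad` (alt-allele read depth) and `dp` (site read depth), one
#'   matrix column per sample in manifest order.
#' @export
read_vcf <- function(path, manifest) {
  manifest <- validate_manifest(manifest)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(vcf@gt)[-1]
  extra <- setdiff(vcf_samples, manifest$sample_id)
  if (length(extra) > 0)
    abort(paste0("VCF sample(s) absent from manifest: ", paste(extra, collapse = ", ")))
  missing <- setdiff(manifest$sample_id, vcf_samples)
  if (length(missing) > 0)
    abort(paste0("manifest sample(s) absent from VCF: ", paste(missing, collapse = ", ")))

  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  use_ad <- "AD" %in% fmt
  use_aoro <- all(c("AO", "RO") %in% fmt)
  if (!use_ad && !use_aoro) {
    site1 <- paste0(fix[1, "CHROM"], ":", fix[1, "POS"])
    abort(paste0("no per-sample depth fields (AD, or AO/RO) in VCF; first site ", site1))
  }

  n_site <- nrow(fix)
  if (use_ad) {
    ad_str <- vcfR::extract.gt(vcf, element = "AD")
  } else {
    ao_str <- vcfR::extract.gt(vcf, element = "AO")
    ro_str <- vcfR::extract.gt(vcf, element = "RO")
  }

  split_counts <- function(s) {
    # "6,4" -> c(6, 4); missing entries -> integer(0)
    if (is.na(s) || s == "." || s == "") return(integer(0))
    suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
  }

  out <- vector("list", n_site)
  for (i in seq_len(n_site)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    k <- length(alts)
    ns <- length(vcf_samples)
    ad_m <- matrix(0L, k, ns)
    dp_m <- matrix(0L, k, ns)
    for (j in seq_len(ns)) {
      if (use_ad) {
        parts <- split_counts(ad_str[i, j])
        if (length(parts) == 0) next
        parts[is.na(parts)] <- 0L
        tot <- sum(parts)
        dp_m[, j] <- tot
        # AD order: ref, alt1, alt2, ...
        for (a in seq_len(k)) ad_m[a, j] <- if (length(parts) >= a + 1) parts[a + 1] else 0L
      } else {
        ao <- split_counts(ao_str[i, j])
        ro <- split_counts(ro_str[i, j])
        if (length(ao) == 0 && length(ro) == 0) next
        ao[is.na(ao)] <- 0L
        ro <- if (length(ro) == 0 || is.na(ro[1])) 0L else ro[1]
        tot <- ro + sum(ao)
        dp_m[, j] <- tot
        for (a in seq_len(k)) ad_m[a, j] <- if (length(ao) >= a) ao[a] else 0L
      }
    }
    out[[i]] <- list(chrom = rep(fix[i, "CHROM"], k),
                     pos = rep(as.integer(fix[i, "POS"]) - 1L, k),
                     ref = rep(fix[i, "REF"], k), alt = alts,
                     ad = ad_m, dp = dp_m)
  }
  ad <- do.call(rbind, lapply(out, `[[`, "ad"))
  dp <- do.call(rbind, lapply(out, `[[`, "dp"))
  tab <- new_variant_table(
    chrom = unlist(lapply(out, `[[`, "chrom")),
    pos = unlist(lapply(out, `[[`, "pos")),
    ref = unlist(lapply(out, `[[`, "ref")),
    alt = unlist(lapply(out, `[[`, "alt")),
    ad = ad, dp = dp, samples = vcf_samples)
  # reorder depth columns to manifest order
  tab$ad <- tab$ad[, manifest$sample_id, drop = FALSE]
  tab$dp <- tab$dp[, manifest$sample_id, drop = FALSE]
  tab
}

#' Write a variant table as VCF
#'
#' Emits one biallelic record per row with an `AD` FORMAT field
#' (`ref_depth,alt_depth` with `ref_depth = dp - ad`), so that
#' `read_vcf(write_vcf(x))` round-trips positions, alleles and depths.
#'
#' @param table A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  samples <- colnames(table$ad)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=flaxfta",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(table) == 0) return(invisible(path))
  ref_d <- table$dp - table$ad
  gt <- matrix(paste0(ref_d, ",", table$ad), nrow = nrow(table))
  body <- cbind(table$chrom, table$pos + 1L, ".", table$ref, table$alt,
                ".", "PASS", ".", "AD", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a sample manifest TSV
#' @param manifest A manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene panel as BED6+1
#' @param panel A panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(panel[, c("chrom", "start", "end", "gene_id", "family", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
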