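#' Euclidean distances between variety VAF profiles
#'
#' Distance between two varieties is the Euclidean distance between their
#' VAF vectors across variants.  Missing VAFs (zero-depth sites) are handled
#' pairwise-complete with rescaling to the full variant count,
#' `d = sqrt(D / m_used * m_total)` where `D` sums squared differences over
#' the mutually present variants — the average squared difference is
#' extrapolated to the profile length so sparsely covered pairs are
#' comparable with dense ones.  `missing = "zero"` instead imputes missing
#' VAFs as 0.
#'
#' @param vaf A VAF tibble ([compute_vaf()]) or a variants x samples matrix.
#' @param missing `"pairwise"` (default) or `"zero"`.
#' @return A samples x samples distance matrix.
#' @export
vaf_distance <- function(vaf, missing = c("pairwise", "zero")) {
  missing <- match.arg(missing)
  x <- if (is.matrix(vaf)) vaf else vaf$vaf
  if (ncol(x) < 2) abort("need at least 2 samples")
  m_total <- nrow(x)
  if (missing == "zero") x[is.na(x)] <- 0
  present <- !is.na(x)
  x0 <- x
  x0[!present] <- 0
  m <- crossprod(present)            # mutually present counts
  s2 <- crossprod(x0^2, present)     # sum_i x_i^2 over mutual support
  d2 <- s2 + t(s2) - 2 * crossprod(x0)
  off <- m == 0 & !diag(TRUE, ncol(x))
  if (any(off)) {
    pair <- which(off, arr.ind = TRUE)[1, ]
    abort(paste0("samples ", colnames(x)[pair[1]], " and ", colnames(x)[pair[2]],
                 " share no mutually observed variants"))
  }
  scale <- m_total / pmax(m, 1)
  d <- sqrt(pmax(d2 * scale, 0))
  diag(d) <- 0
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Ward (ward.D2) hierarchical clustering
#'
#' Agglomerative clustering by Ward's minimum variance criterion on
#' Euclidean distances (the `ward.D2` variant, which squares the
#' dissimilarities inside the Lance-Williams update).
#'
#' @param distances A symmetric distance matrix or `dist` object.
#' @return An `hclust` tree (merge list, heights, leaf order).
#' @export
ward_cluster <- function(distances) {
  d <- as.dist(distances)
  if (any(!is.finite(d))) abort("non-finite distances")
  hclust(d, method = "ward.D2")
}

#' Similarity matrix from distances
#'
#' `similarity = 1 - d / max(d)`: 1 for identical profiles, 0 for the most
#' distant pair.  An all-zero distance matrix yields the identity similarity
#' with a warning.
#'
#' @param distances A symmetric distance matrix.
#' @return A similarity matrix with attribute `metric = "max_normalized_complement"`.
#' @export
similarity_from_distance <- function(distances) {
  mx <- max(distances)
  if (mx == 0) {
    warn("all distances are zero; similarity is the identity")
    s <- matrix(1, nrow(distances), ncol(distances),
                dimnames = dimnames(distances))
  } else {
    s <- 1 - distances / mx
  }
  attr(s, "metric") <- "max_normalized_complement"
  s
}

#' Cluster composition against the type labels
#'
#' Cuts the tree at `k` clusters and reports each cluster's fiber/linseed
#' make-up; purity is the majority fraction.
#'
#' @param tree An `hclust` tree over the manifest's samples.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param manifest A manifest tibble.
#' @return A tibble: `cluster`, `n_samples`, `n_fiber`, `n_linseed`,
#'   `majority_type`, `purity`.
#' @export
cluster_composition <- function(tree, k, manifest) {
  n <- length(tree$order)
  if (k < 1 || k > n) abort(paste0("k must lie in [1, ", n, "]"))
  cl <- cutree(tree, k = k)
  tibble(sample_id = names(cl), cluster = unname(cl)) |>
    left_join(validate_manifest(manifest), by = "sample_id") |>
    group_by(.data$cluster) |>
    summarise(n_samples = n(),
              n_fiber = sum(.data$type_label == "fiber"),
              n_linseed = sum(.data$type_label == "linseed"),
              .groups = "drop") |>
    mutate(majority_type = ifelse(.data$n_fiber >= .data$n_linseed,
                                  "fiber", "linseed"),
           purity = pmax(.data$n_fiber, .data$n_linseed) / .data$n_samples)
}

#' Write an hclust tree as Newick
#'
#' Branch lengths derive from the merge heights via [ape::as.phylo()].
#'
#' @param tree An `hclust` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
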