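#' Polymorphism density per gene family
#'
#' Per-kilobase polymorphism densities of a census, one box per family.
#'
#' @param census A census tibble ([census_polymorphisms()]).
#' @return A ggplot.
#' @export
plot_census <- function(census) {
  ggplot2::ggplot(census,
                  ggplot2::aes(x = .data$family, y = .data$density_per_kb)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "polymorphisms per kb of gene region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Genetic-similarity heatmap between varieties
#'
#' The green-yellow-red similarity view: green for the most similar pairs,
#' red for the least.
#'
#' @param similarity A similarity matrix ([similarity_from_distance()]).
#' @param manifest Optional manifest; when given, samples are ordered by
#'   type so the two groups form blocks.
#' @return A ggplot.
#' @export
plot_similarity <- function(similarity, manifest = NULL) {
  ord <- rownames(similarity)
  if (!is.null(manifest))
    ord <- manifest$sample_id[order(manifest$type_label)]
  df <- as.data.frame(as.table(similarity[ord, ord]))
  names(df) <- c("a", "b", "similarity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("red", "yellow", "darkgreen"),
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Expression heatmap of a clustered matrix
#'
#' @param hm Result of [cluster_heatmap()] (or a plain centred matrix).
#' @return A ggplot with the leaf-ordered matrix as tiles.
#' @export
plot_expression_heatmap <- function(hm) {
  m <- if (is.list(hm)) hm$matrix else hm
  df <- as.data.frame(as.table(m))
  names(df) <- c("gene", "sample", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 CPM\n(centred)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn screen_associations Per-gene FTA counts (publication-table
#'   view) as a bar chart; genes without FTA polymorphisms are omitted.
#' @param object An `fta_screen`.
#' @param max_genes Show at most this many genes, by descending count.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fta_screen <- function(object, max_genes = 40, ...) {
  df <- fta_report(object$genes) |>
    arrange(dplyr::desc(.data$n_fta_strong)) |>
    head(max_genes) |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_fta_strong, y = .data$gene_id,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "FTA polymorphisms (|r_s| >= 0.4)", y = NULL) +
    ggplot2::theme_minimal()
}
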