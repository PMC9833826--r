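# ggplot2 figure helpers. Plots are presentation artifacts; every assertion
# in the package runs on the underlying tables.

#' Manhattan plot of an association scan
#'
#' @param assoc Association tibble (`chrom, pos, p`), e.g. one feature's rows
#'   from [map_qtl()].
#' @param highlight_q Optional q cut; points below it are coloured.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, highlight_q = 0.1) {
  assoc$chrom_f <- chrom_order(assoc$chrom)
  assoc$sig <- !is.na(assoc$q) & assoc$q < highlight_q
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sig), size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom_f),
      scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.spacing.x = ggplot2::unit(1, "pt")
    )
}

#' Mirrored protein/trait Manhattan plot
#'
#' Protein scan above the axis, trait scan below — the side-by-side view used
#' to eyeball shared loci.
#'
#' @param protein_assoc,trait_assoc Association tibbles for one protein and
#'   one trait.
#' @return A ggplot object.
#' @export
plot_mirrored_manhattan <- function(protein_assoc, trait_assoc) {
  protein_assoc$panel_y <- -log10(protein_assoc$p)
  trait_assoc$panel_y <- log10(trait_assoc$p)
  both <- dplyr::bind_rows(
    dplyr::mutate(protein_assoc, scan = "protein"),
    dplyr::mutate(trait_assoc, scan = "trait")
  )
  both$chrom_f <- chrom_order(both$chrom)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$pos, y = .data$panel_y, colour = .data$scan)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom_f), scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "chromosome", y = expression("" %+-% -log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Trans-hotspot density track
#'
#' @param hotspots Bin tibble from [detect_hotspots()].
#' @return A ggplot object (empty data gives an empty plot).
#' @export
plot_hotspots <- function(hotspots) {
  if (nrow(hotspots) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no trans calls") +
      ggplot2::theme_void())
  }
  hotspots$chrom_f <- chrom_order(hotspots$chrom)
  ggplot2::ggplot(hotspots, ggplot2::aes(x = .data$start, y = .data$n_features,
    fill = .data$flagged)) +
    ggplot2::geom_col(width = hotspots$end - hotspots$start, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom_f), scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "chromosome", y = "trans-regulated features / bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' OPLS loading plot with correlation-filter highlighting
#'
#' Predictive loading (p1) on x, orthogonal loading (o1) on y; proteins
#' passing the correlation filter are highlighted.
#'
#' @param loadings Tibble from [export_loadings()].
#' @return A ggplot object.
#' @export
plot_loadings <- function(loadings) {
  ggplot2::ggplot(loadings, ggplot2::aes(x = .data$p1, y = .data$o1)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = "correlation filter") +
    ggplot2::labs(x = "predictive loading (p1)", y = "orthogonal loading (o1)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_loadings
#' @param object An `opls_fit`.
#' @param ... Unused.
#' @method autoplot opls_fit
#' @export
autoplot.opls_fit <- function(object, ...) {
  l <- object$loadings
  l$selected <- FALSE
  plot_loadings(l) + ggplot2::guides(colour = "none")
}
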