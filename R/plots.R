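#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA scores
#'
#' Scatter of the first two principal components, coloured by line —
#' the standard population-structure view in which samples from the
#' same line cluster tightly.
#'
#' @param object A `snp_pca` from [pca_genotypes()].
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snp_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  lab <- sprintf("%s (%.1f%%)", pcs, 100 * object$explained[components])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]],
                               colour = .data$line)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "line") +
    ggplot2::theme_minimal()
}

#' Plot a selected panel along the genome
#'
#' Marker positions per chromosome coloured by provenance (which
#' backbone pass or line filling placed each SNP).
#'
#' @param object A `panel_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panel_selection <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$pos / 1e6, .data$chrom,
                               colour = .data$provenance)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "placed by") +
    ggplot2::theme_minimal()
}

#' Cumulative spacing curves
#'
#' Cumulative fraction of markers and of genome coverage as functions
#' of inter-marker gap size.
#'
#' @param stats Result of [spacing_stats()].
#' @return A ggplot.
#' @export
plot_spacing_cumulative <- function(stats) {
  df <- stats$cumulative |>
    tidyr::pivot_longer(c("snp_fraction", "genome_coverage"),
                        names_to = "curve", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$g, .data$fraction,
                                   colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inter-marker gap (bases)", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Per-chromosome density bars
#'
#' Side-by-side SNPs/Mb and SNPs/cM per chromosome; an
#' evenly-distributed-in-cM panel shows flat SNPs/cM while SNPs/Mb
#' varies with the recombination rate.
#'
#' @param density Result of [density_by_chromosome()].
#' @return A ggplot.
#' @export
plot_density_by_chromosome <- function(density) {
  df <- density |>
    tidyr::pivot_longer(c("snps_per_mb", "snps_per_cm"),
                        names_to = "unit", values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(.data$chrom, .data$density,
                                   fill = .data$unit)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "SNP density") +
    ggplot2::theme_minimal()
}

#' MAF histogram plot
#'
#' @param dist Result of [maf_distribution()].
#' @return A ggplot.
#' @export
plot_maf_distribution <- function(dist) {
  p <- ggplot2::ggplot(dist,
                       ggplot2::aes((.data$bin_low + .data$bin_high) / 2,
                                    .data$count)) +
    ggplot2::geom_col(width = 0.045) +
    ggplot2::labs(x = "minor allele frequency", y = "SNPs") +
    ggplot2::theme_minimal()
  if ("group" %in% names(dist)) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}
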