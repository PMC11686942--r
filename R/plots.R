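# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_abline labs theme_minimal scale_colour_viridis_c facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a distance correlogram
#' @param object A `wealth_correlogram`. @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.wealth_correlogram <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_mid, y = .data$correlation)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line(colour = "grey40") +
    geom_point(aes(size = .data$n_pairs)) +
    labs(x = "distance (m)", y = "pair correlation of wealth",
         size = "pairs") +
    theme_minimal()
}

#' Manhattan plot of a GWAS scan
#' @param object A `gwas_result`. @param alpha Family-wise rate for the
#'   Bonferroni line. @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gwas_result <- function(object, alpha = 0.05, ...) {
  ok <- object[!is.na(object$p), ]
  ok$chrom <- factor(ok$chrom, levels = unique(ok$chrom))
  thr <- bonferroni_threshold(alpha, nrow(ok))
  ok <- dplyr::arrange(ok, .data$chrom, .data$pos)
  ok$index <- seq_len(nrow(ok))
  ggplot(ok, aes(x = .data$index, y = -log10(.data$p),
                 colour = as.integer(.data$chrom) %% 2 == 0)) +
    geom_point(size = 0.6, show.legend = FALSE) +
    geom_hline(yintercept = -log10(thr), linetype = 2) +
    labs(x = "SNP", y = expression(-log[10](p))) +
    theme_minimal()
}

#' Null envelope of the spatial simulation against the observed slope
#' @param object A `spatial_null`. @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.spatial_null <- function(object, ...) {
  df <- tibble::tibble(slope = object$slopes)
  ggplot(df, aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_slope, colour = "#1b7837",
                        linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$envelope, linetype = 2) +
    labs(x = "natal to breeding wealth slope (null replicates)",
         y = "count") +
    theme_minimal()
}

#' Map of territories coloured by wealth
#'
#' @param map Territory map.
#' @param field Optional wealth field; the given `year` is shown.
#' @param year Year to display (defaults to the first in `field`).
#' @return A ggplot.
#' @export
plot_territories <- function(map, field = NULL, year = NULL) {
  if (is.null(field)) {
    return(ggplot(map, aes(.data$x, .data$y)) + geom_point() +
             labs(x = "x (m)", y = "y (m)") + theme_minimal())
  }
  year <- year %||% min(field$year)
  f <- field[field$year == year, ]
  df <- dplyr::inner_join(map, f, by = "territory_id")
  ggplot(df, aes(.data$x, .data$y, colour = .data$wealth)) +
    geom_point(size = 2) +
    scale_colour_viridis_c() +
    labs(x = "x (m)", y = "y (m)", colour = "wealth",
         title = paste("year", year)) +
    theme_minimal()
}
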