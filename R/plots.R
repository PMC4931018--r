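#' Plot a stacked splice-site methylation profile
#'
#' One line per context, faceted by site class (donor/acceptor) and strand
#' track, mirroring the conventional splice-site metaprofile figure.
#'
#' @param object An `iso_junction_profile` from [stack_junctions()].
#' @param strand_rel Which tracks to show (default all three).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iso_junction_profile <- function(object, strand_rel = c("combined", "sense", "antisense"), ...) {
  df <- as_tibble(object) %>%
    filter(.data$strand_rel %in% .env$strand_rel) %>%
    mutate(site_class = factor(.data$site_class, levels = c("donor", "acceptor")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$level,
                                   colour = .data$context)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strand_rel),
                        cols = ggplot2::vars(.data$site_class)) +
    ggplot2::labs(x = "position relative to splice site (bp)",
                  y = "methylation level C/(C+T)", colour = "context") +
    ggplot2::theme_minimal()
}

#' Plot a rarefaction curve
#'
#' @param object An `iso_rarefaction` from [rarefy()].
#' @param ... Unused.
#' @return A ggplot object with the mean curve and a +-1 SD ribbon.
#' @export
autoplot.iso_rarefaction <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$mean_units)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_units - .data$sd_units,
                                      ymax = .data$mean_units + .data$sd_units),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "subsampled reads",
                  y = paste0("distinct ", attr(object, "unit"), "s discovered")) +
    ggplot2::theme_minimal()
}

#' Bar plot of structural category counts
#'
#' @param classified Output of [classify_isoforms()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(classified) {
  df <- classified %>% count(.data$group, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "isoforms") +
    ggplot2::theme_minimal()
}

#' Plot a metagene methylation profile
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object: 3 x `bins` bins on a shared axis, faceted by
#'   group.
#' @export
plot_metagene <- function(profile) {
  bins <- max(profile$bin)
  df <- profile %>%
    mutate(x = as.integer(.data$region) * bins - bins + .data$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$level,
                                   colour = .data$context)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(bins, 2 * bins) + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "TSS-1kb .. body .. TTS+1kb (bins)",
                  y = "methylation level C/(C+T)") +
    ggplot2::theme_minimal()
}
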