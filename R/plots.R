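#' Histogram of between-ecotype FST per country
#'
#' Distribution of the replicate-averaged between-ecotype FST across
#' contigs, faceted by country; the long right tail holds the candidate
#' targets of divergent selection.
#'
#' @param cfst Country-level FST tibble ([country_fst()]).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_fst_distribution <- function(cfst, bins = 60) {
  ggplot2::ggplot(cfst, ggplot2::aes(x = .data$fst_mean)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$country)) +
    ggplot2::labs(x = expression(F[ST] ~ "between ecotypes (replicate mean)"),
                  y = "contigs") +
    ggplot2::theme_minimal()
}

#' Replicate FST scatter per country
#'
#' Per-contig between-ecotype FST of replicate pair 1 against replicate
#' pair 2, optionally highlighting replicate-consistent outliers.
#'
#' @param cfst Country-level FST tibble ([country_fst()]).
#' @param outliers Optional outlier tibble from [detect_outliers()].
#' @return A ggplot object.
#' @export
plot_replicate_fst <- function(cfst, outliers = NULL) {
  cfst$outlier <- if (is.null(outliers)) FALSE else {
    paste(cfst$country, cfst$contig) %in%
      paste(outliers$country, outliers$contig)
  }
  ggplot2::ggplot(cfst, ggplot2::aes(x = .data$fst_rep1, y = .data$fst_rep2,
                                     colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::facet_wrap(ggplot2::vars(.data$country)) +
    ggplot2::labs(x = expression(F[ST] ~ "replicate pair 1"),
                  y = expression(F[ST] ~ "replicate pair 2")) +
    ggplot2::theme_minimal()
}

#' Observed versus chance outlier sharing across quantiles
#'
#' Observed sharing proportion per country pair against the threshold
#' quantile, with the hypergeometric 95% chance band.
#'
#' @param scan A `pool_scan` object.
#' @return A ggplot object.
#' @export
plot_sharing <- function(scan) {
  sharing <- tidy(scan)
  sharing$pair <- paste(sharing$set_a, sharing$set_b, sep = "-")
  sharing$prop <- sharing$observed_shared / pmax(sharing$n_a, 1)
  sharing$lo <- sharing$ci_low / pmax(sharing$n_a, 1)
  sharing$hi <- sharing$ci_high / pmax(sharing$n_a, 1)
  ggplot2::ggplot(sharing, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prop)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = "threshold quantile",
                  y = "shared / focal outliers (band: 95% chance)") +
    ggplot2::theme_minimal()
}

#' Histogram of per-contig SNP-difference correlations
#'
#' Distribution of the per-contig Pearson correlations of ecotype
#' allele-frequency differences between countries, for all contigs and,
#' optionally, restricted to shared outlier contigs.
#'
#' @param corr Correlation tibble ([contig_correlation()]).
#' @param shared Optional character vector of shared outlier contigs to
#'   overlay.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_snp_correlations <- function(corr, shared = NULL, bins = 20) {
  p <- ggplot2::ggplot(corr, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::facet_wrap(ggplot2::vars(.data$country_pair), scales = "free_y") +
    ggplot2::labs(x = "per-contig correlation of SNP ecotype differences",
                  y = "contigs") +
    ggplot2::theme_minimal()
  if (!is.null(shared)) {
    p <- p + ggplot2::geom_histogram(
      data = corr[corr$contig %in% shared, ], bins = bins,
      fill = "firebrick", alpha = 0.8
    )
  }
  p
}

#' Autoplot method for pool_scan objects
#'
#' @param object A `pool_scan`.
#' @param type One of `"sharing"`, `"fst"`, `"replicates"`,
#'   `"correlations"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pool_scan
#' @export
autoplot.pool_scan <- function(object, type = c("sharing", "fst",
                                                "replicates", "correlations"),
                               ...) {
  type <- match.arg(type)
  switch(type,
    sharing = plot_sharing(object),
    fst = plot_fst_distribution(object$country_fst),
    replicates = plot_replicate_fst(object$country_fst,
                                    object$outliers[[1]]),
    correlations = plot_snp_correlations(object$snp_correlations)
  )
}
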