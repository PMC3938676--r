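#' Plot the site-filter surface of a Discovery run
#'
#' Minor allele frequency against the inbreeding coefficient F_IT, coloured
#' by retention: paralog-merged loci sit at strongly negative F_IT,
#' error-prone sites at low MAF.
#'
#' @param object A `gbs_discovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_discovery <- function(object, ...) {
  d <- object$sites[!is.na(object$sites$f_it), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$maf, y = .data$f_it,
                                  colour = .data$retained)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "minor allele frequency", y = expression(F[IT]),
                  colour = "retained") +
    ggplot2::theme_minimal()
}

#' Plot the per-SNP error-rate distribution
#' @param object A `gbs_error_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_error_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$error_rate), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$error_rate)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::labs(x = "per-SNP error rate", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Plot per-taxon depth totals of a TBT
#' @param tbt A `gbs_tbt`.
#' @return A ggplot of total matched depth per taxon (blank controls stand
#'   out as near-zero bars).
#' @export
plot_taxon_depth <- function(tbt) {
  d <- tibble::tibble(taxon = tbt$taxa, depth = colSums(tbt$depth))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$taxon,
                                                     .data$depth),
                                  y = .data$depth)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "total matched depth") +
    ggplot2::theme_minimal(base_size = 8)
}
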