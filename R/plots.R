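#' Plot a genome scan
#'
#' Wald statistic against map position, faceted by chromosome, with the
#' genome-wide threshold drawn when supplied.
#'
#' @param object A `qtl_scan` tibble.
#' @param threshold Optional `threshold_spec` (or numeric Wald threshold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object[!object$untestable, ],
                       ggplot2::aes(x = .data$position, y = .data$wald)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (cM)", y = "Wald statistic",
      title = sprintf("%s scan%s", attr(object, "kind") %||% "genome",
                      if (!is.null(attr(object, "covariate")))
                        paste0(" × ", attr(object, "covariate")) else "")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "threshold_spec")) threshold$wald_threshold
           else threshold
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Responsiveness effects across the covariate range
#'
#' For each responsiveness QTL, the predicted allele contrast (+1 allele
#' minus the population mean) as a line over the observed covariate range:
#' slope `b` for the +1 allele and `-b` for the -1 allele, so the vertical
#' spread at the range edges equals the normalised effect on either side of
#' zero.
#'
#' @param records A `qtl_records` tibble of responsiveness QTL.
#' @param covariates The `climatic_covariates` used in the scans.
#' @return A ggplot object.
#' @export
plot_responsiveness <- function(records, covariates) {
  stopifnot(all(records$type == "responsiveness"))
  dat <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    cv <- covariates[covariates$covariate == records$covariate[i], ]
    xr <- range(cv$value)
    centre <- mean(cv$value)
    purrr::map_dfr(c(`+1` = 1, `-1` = -1), function(a) {
      tibble::tibble(qtl = records$name[i], covariate = records$covariate[i],
                     allele = if (a > 0) "+1" else "-1",
                     x = xr, y = a * records$effect[i] * (xr - centre))
    })
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$allele)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$qtl), scales = "free") +
    ggplot2::labs(x = "covariate value", y = "allele effect (trait units)") +
    ggplot2::theme_minimal()
}
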