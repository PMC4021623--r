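# ggplot2 views of the pipeline results.

#' Plot mitochondrial PVE against significant-variant counts
#'
#' The consistency view of the two stages: per-trait mitochondrial PVE (bars,
#' with standard-error whiskers) and the number of significantly associated
#' mtSNPs (points, rescaled onto a secondary axis), with the
#' expected-by-chance count as a dashed reference line.
#'
#' @param summary_tbl Output of [render_summary()] (or a `mtphewas_report`).
#' @return A ggplot object.
#' @export
plot_pve_counts <- function(summary_tbl) {
  if (inherits(summary_tbl, "mtphewas_report")) {
    summary_tbl <- render_summary(summary_tbl)
  }
  d <- summary_tbl
  scale_f <- max(d$pve_mt + ifelse(is.na(d$pve_mt_se), 0, d$pve_mt_se),
                 na.rm = TRUE) /
    max(d$n_significant, 1, na.rm = TRUE)
  exp_line <- if ("expected_by_chance" %in% names(d)) d$expected_by_chance[1] else NA
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$trait, -.data$pve_mt))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pve_mt), fill = "grey60") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$pve_mt - .data$pve_mt_se, 0),
                   ymax = .data$pve_mt + .data$pve_mt_se),
      width = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_significant * scale_f),
                        size = 2, na.rm = TRUE) +
    {if (is.finite(exp_line))
      ggplot2::geom_hline(yintercept = exp_line * scale_f, linetype = "dashed")} +
    ggplot2::scale_y_continuous(
      name = "mitochondrial PVE",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "significant mtSNPs")) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Manhattan-style view of one trait's mtSNP scan
#'
#' -log10 p-values by mitochondrial position, significance threshold dashed.
#'
#' @param scan An `mt_scan` tibble from [run_mt_scan()].
#' @param trait Trait to plot (default: first in the scan).
#' @param alpha Significance threshold line.
#' @return A ggplot object.
#' @export
plot_mt_scan <- function(scan, trait = NULL, alpha = 0.05) {
  if (is.null(trait)) trait <- scan$trait[1]
  d <- scan[scan$trait == trait & scan$testable, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "mtDNA position (bp)", y = "-log10 p", title = trait) +
    ggplot2::theme_minimal()
}

#' @rdname plot_pve_counts
#' @param object A `mtphewas_report`.
#' @param ... Unused.
#' @export
autoplot.mtphewas_report <- function(object, ...) plot_pve_counts(object)
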