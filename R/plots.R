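#' Dual-criterion overview plot
#'
#' One point per metric and analytical approach, -log10 p against the
#' metric, with the family's Bonferroni threshold as a dashed line;
#' dual-positive metrics are highlighted.
#'
#' @param stats a `cohort_stats` object.
#' @return A ggplot.
#' @export
plot_dual_criterion <- function(stats) {
  tab <- stats$table
  long <- dplyr::bind_rows(
    dplyr::transmute(tab, family = .data$family, metric = .data$metric,
                     approach = "raw", p = .data$p_raw,
                     threshold = .data$threshold,
                     positive = .data$positive),
    dplyr::transmute(tab, family = .data$family, metric = .data$metric,
                     approach = "control-subtracted", p = .data$p_ctrl,
                     threshold = .data$threshold,
                     positive = .data$positive))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = -log10(.data$p),
                                     shape = .data$approach,
                                     colour = .data$positive)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -log10(.data$threshold)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(y = expression(-log[10](p)), x = NULL,
                  colour = "dual-positive") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Sparsity sweep diagnostics plot
#'
#' Per-subject small-world sigma across the candidate sparsity levels,
#' with the sigma > 1.1 criterion and the validated levels marked.
#'
#' @param sweep a `sparsity_sweep` object.
#' @param sigma_min criterion line (default 1.1).
#' @return A ggplot.
#' @export
plot_sparsity_sweep <- function(sweep, sigma_min = 1.1) {
  ggplot2::ggplot(sweep$levels,
                  ggplot2::aes(x = .data$sparsity, y = .data$sigma,
                               group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pass)) +
    ggplot2::geom_hline(yintercept = sigma_min, linetype = "dashed") +
    ggplot2::labs(x = "sparsity", y = expression(sigma),
                  colour = "passes") +
    ggplot2::theme_minimal()
}
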