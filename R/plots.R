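# Diagnostic figures for cohorts and results.

#' Group comparison of percent enrichment
#'
#' Box-and-jitter plot of percent 13C enrichment by metabolite and group,
#' faceted by pathway domain (glycolysis, TCA turn 1, TCA turn 2).
#'
#' @param enrichment Enrichment tibble with columns `metabolite`, `domain`,
#'   `group`, `enrichment` (as in `run_pipeline()$enrichment`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  d <- enrichment[!is.na(enrichment$enrichment), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metabolite, y = .data$enrichment,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~domain, scales = "free") +
    ggplot2::labs(x = NULL, y = "13C enrichment (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Enrichment correlation scatter for one metabolite pair
#'
#' @param enrichment Enrichment tibble (see [plot_enrichment()]).
#' @param x,y Metabolite ids.
#' @param turn TCA turn of both metabolites (1 for glycolytic).
#' @return A ggplot object with per-group regression lines.
#' @export
plot_correlation <- function(enrichment, x, y, turn = 1) {
  w <- tidyr::pivot_wider(
    dplyr::select(
      dplyr::filter(enrichment, .data$metabolite %in% c(x, y),
                    .data$turn == !!turn),
      "sample", "group", "metabolite", "enrichment"),
    names_from = "metabolite", values_from = "enrichment")
  ggplot2::ggplot(w, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                  colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = paste0(x, " enrichment (%)"),
                  y = paste0(y, " enrichment (%)"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.glucotrace_results <- function(object, ...) {
  plot_enrichment(object$enrichment)
}

#' @export
autoplot.glucotrace_cohort <- function(object, ...) {
  tr <- dplyr::left_join(object$traces,
                         dplyr::select(object$trace_meta, "sample", "group",
                                       "enzyme"),
                         by = c("sample", "enzyme"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$absorbance,
                                   group = .data$sample,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::facet_wrap(~enzyme, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "absorbance (AU)", colour = NULL) +
    ggplot2::theme_minimal()
}
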