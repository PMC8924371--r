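#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank plot of gene normZ scores
#'
#' The classic screen overview: genes ordered by normZ with the directional
#' FDR hit boundaries marked, optionally highlighting a gene set of interest
#' (e.g. a pathway) along the ranking.
#'
#' @param scores A [gene_scores()] tibble.
#' @param fdr_threshold FDR threshold used for the hit boundaries.
#' @param highlight Optional character vector of gene ids to emphasise.
#' @return A ggplot object.
#' @export
plot_rank_scores <- function(scores, fdr_threshold = 0.1, highlight = NULL) {
  depl <- call_hits(scores, "depleted", fdr_threshold)
  enr <- call_hits(scores, "enriched", fdr_threshold)
  df <- dplyr::mutate(
    scores,
    status = dplyr::case_when(
      .data$fdr_depletion < fdr_threshold ~ "depleted",
      .data$fdr_enrichment < fdr_threshold ~ "enriched",
      TRUE ~ "ns"
    )
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$normZ,
                                        colour = .data$status)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(depleted = "#c0392b",
                                            enriched = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "gene rank (most depleted first)", y = "normZ",
                  colour = NULL) +
    ggplot2::theme_minimal()
  for (b in c(depl$boundary_normZ, enr$boundary_normZ)) {
    if (!is.na(b)) p <- p + ggplot2::geom_hline(yintercept = b,
                                                linetype = "dashed",
                                                colour = "grey40")
  }
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$gene_id %in% highlight),
      colour = "#8e44ad", size = 1.6
    )
  }
  p
}

#' @describeIn fit_biphasic Plot the fitted growth-vs-pHe curve over the
#'   wells, with the optimum and pH50 marked.
#' @param object A `biphasic_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.biphasic_fit <- function(object, ...) {
  grid <- tibble::tibble(phe = seq(min(object$data$phe) - 0.3,
                                   max(object$data$phe) + 0.3,
                                   length.out = 200))
  grid$g <- biphasic_growth(grid$phe, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$phe, y = .data$absorbance)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$g),
                       colour = "#2c3e50") +
    ggplot2::geom_point(colour = "#c0392b", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$ph_opt, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$ph50, linetype = "dashed",
                        colour = if (object$censored) "grey60" else "#c0392b") +
    ggplot2::labs(x = "extracellular pH", y = "growth (assay units)",
                  title = sprintf("pH_opt %.2f | pH50 %.2f%s", object$ph_opt,
                                  object$ph50,
                                  if (object$censored) " (censored)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot a medium pH / O2 photometry time course
#'
#' @param trace A `photometry_trace` from [simulate_phot_timecourse()].
#' @return A ggplot object with pH and O2 panels.
#' @export
plot_phot_trace <- function(trace) {
  long <- trace |>
    dplyr::select("time_h", "ph", "o2_mM") |>
    tidyr::pivot_longer(-"time_h", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(ph = "medium pH", o2_mM = "O2 (mM)"))) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
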