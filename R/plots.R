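#' Volcano plot of the meta-signature
#'
#' Combined log2 fold-change against -log10 adjusted p, with signature
#' genes highlighted and the selection thresholds drawn.
#'
#' @param object A `meta_signature` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_signature
#' @export
autoplot.meta_signature <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combined_log2fc,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$in_signature)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$fc_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$q_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey65"),
                                 name = "in signature") +
    ggplot2::labs(x = "combined log2 fold-change (tumor - normal)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' RGES distributions across profiling conditions
#'
#' Boxplots of profile-level RGES split by dose or duration relative to
#' the 10 uM / 24 h reference condition.
#'
#' @param records Tibble from [score_profiles()].
#' @param factor `"dose"` or `"duration"`.
#' @param ref_dose,ref_duration Dichotomization thresholds.
#' @return A ggplot object.
#' @export
plot_rges_conditions <- function(records, factor = c("dose", "duration"),
                                 ref_dose = 10, ref_duration = 24) {
  factor <- match.arg(factor)
  d <- records |>
    mutate(group = if (factor == "dose") {
      if_else(.data$dose_um < ref_dose,
              sprintf("< %g uM", ref_dose), sprintf(">= %g uM", ref_dose))
    } else {
      if_else(.data$duration_h < ref_duration,
              sprintf("< %g h", ref_duration), sprintf(">= %g h", ref_duration))
    })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$rges)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = factor, y = "RGES") +
    ggplot2::theme_minimal()
}

#' Reversal-gene heatmap layout
#'
#' Normalized rank positions of the screened genes across compounds, with
#' compound columns ordered by median IC50 (most active on the left) and
#' genes ordered by direction then worst-trial q.
#'
#' @param positions Tibble from [normalized_rank_positions()].
#' @param classes Tibble with `compound`, `median_value`, `label`.
#' @param screen Optional `reversal_screen` used to order/annotate genes.
#' @return A ggplot object.
#' @export
plot_reversal_heatmap <- function(positions, classes, screen = NULL) {
  ord <- classes |> arrange(.data$median_value)
  d <- positions |>
    mutate(compound = factor(.data$compound, levels = ord$compound))
  if (!is.null(screen)) {
    gene_ord <- screen$results |>
      arrange(desc(.data$reversed), .data$direction, .data$worst_q)
    d <- d |> mutate(gene_id = factor(.data$gene_id,
                                      levels = rev(gene_ord$gene_id)))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compound, y = .data$gene_id,
                                  fill = .data$position)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rank position") +
    ggplot2::labs(x = "compound (ordered by median IC50)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_text(size = 5))
}

#' Synergy heatmap of a combination screen
#'
#' Predicted sensitivity for every screened drug pair as a symmetric tile
#' map.
#'
#' @param object A `synergy_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synergy_screen
#' @export
autoplot.synergy_screen <- function(object, ...) {
  p <- object$pairs
  d <- bind_rows(
    p |> select(d1 = "drug1", d2 = "drug2", "predicted_sensitivity"),
    p |> select(d1 = "drug2", d2 = "drug1", "predicted_sensitivity")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d1, y = .data$d2,
                                  fill = .data$predicted_sensitivity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "predicted\nsensitivity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
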