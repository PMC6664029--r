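#' Aggregate activity records to one median per compound
#'
#' Activity measurements for a compound vary across cell lines and
#' replicate assays; the per-compound median is used. A single call must
#' contain a single measure type (IC50 or AUC) — mixing them is an error.
#' The even-count median is the mean of the middle pair.
#'
#' @param records Tibble with `compound`, `measure`, `value` (and usually
#'   `cell_line`).
#' @return Tibble with `compound`, `measure`, `median_value`, `n_records`.
#' @export
aggregate_activity <- function(records) {
  stopifnot(all(c("compound", "measure", "value") %in% names(records)))
  if (nrow(records) == 0) abort("no activity records")
  if (dplyr::n_distinct(records$measure) > 1) {
    abort("mixed measures in one aggregation; split IC50 and AUC records")
  }
  if (records$measure[1] == "IC50" && any(records$value <= 0)) {
    abort("IC50 values must be positive")
  }
  records |>
    group_by(.data$compound, .data$measure) |>
    summarise(median_value = median(.data$value), n_records = n(),
              .groups = "drop")
}

#' Classify compounds as active or inactive
#'
#' A compound is active when its median IC50 falls strictly below the
#' threshold (default 10 uM) and inactive at or above it — the usual
#' primary-screening convention under which compounds with IC50 >= 10 uM
#' are not pursued.
#'
#' @param median_ic50 Positive numeric vector of median IC50s (uM).
#' @param threshold Activity threshold in uM.
#' @return Character vector, `"active"` or `"inactive"`.
#' @export
#' @examples
#' classify_activity(c(9.99, 10, 0.5))
classify_activity <- function(median_ic50, threshold = 10) {
  if (any(!is.finite(median_ic50)) || any(median_ic50 <= 0)) {
    abort("median IC50 must be positive and finite")
  }
  if_else(median_ic50 < threshold, "active", "inactive")
}

#' Median activity with active/inactive labels
#'
#' Convenience wrapper: [aggregate_activity()] followed by
#' [classify_activity()] on the medians (IC50 records only).
#'
#' @inheritParams aggregate_activity
#' @param threshold Activity threshold in uM.
#' @return Tibble with `compound`, `median_value`, `label`.
#' @export
activity_classes <- function(records, threshold = 10) {
  agg <- aggregate_activity(records)
  if (agg$measure[1] != "IC50") {
    abort("activity classification is defined on IC50 records")
  }
  agg |>
    mutate(label = classify_activity(.data$median_value, threshold)) |>
    select("compound", "median_value", "label")
}

#' Correlate reversal potency with compound activity
#'
#' Spearman rank correlation between per-compound sRGES and median
#' activity over the compound intersection. A positive correlation means
#' stronger reversers (more negative sRGES) are more active (lower
#' IC50/AUC).
#'
#' @param srges Tibble from [summarize_rges()] (`compound`, `srges`).
#' @param activity Tibble from [aggregate_activity()] (`compound`,
#'   `median_value`).
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
evaluate_reversal_potency <- function(srges, activity) {
  d <- inner_join(srges, activity, by = "compound")
  if (nrow(d) < 3) abort("need >= 3 compounds in the intersection")
  if (sd(d$srges) == 0 || sd(d$median_value) == 0) {
    abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(
    cor.test(d$srges, d$median_value, method = "spearman", exact = FALSE)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Expression similarity between tumor samples and cell lines
#'
#' Restricts both matrices to the shared genes, keeps the `top_k` genes by
#' interquartile range computed across the cell lines, and reports the
#' Spearman correlation of every (tumor sample, cell line) pair over those
#' genes.
#'
#' @param tumor_matrix Genes x samples matrix, log2 scale.
#' @param cellline_matrix Genes x lines matrix, log2 scale.
#' @param top_k Number of most-variable genes to keep (clipped with a
#'   warning when fewer shared genes are available).
#' @return Tibble with `sample_id`, `cell_line`, `rho`.
#' @export
expression_similarity <- function(tumor_matrix, cellline_matrix,
                                  top_k = 5000) {
  shared <- intersect(rownames(tumor_matrix), rownames(cellline_matrix))
  if (length(shared) == 0) abort("no shared genes between matrices")
  if (top_k > length(shared)) {
    warn(sprintf("top_k clipped from %d to %d available shared genes",
                 top_k, length(shared)))
    top_k <- length(shared)
  }
  cl <- cellline_matrix[shared, , drop = FALSE]
  iqr <- apply(cl, 1, IQR)
  keep <- shared[order(-iqr, shared)][seq_len(top_k)]
  tm <- tumor_matrix[keep, , drop = FALSE]
  cl <- cl[keep, , drop = FALSE]
  rho <- cor(tm, cl, method = "spearman")
  as_tibble(rho, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_line",
                        values_to = "rho")
}
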