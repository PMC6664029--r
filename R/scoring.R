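#' Rank a drug profile's genes by differential expression
#'
#' Most up-regulated gene first (rank 1 = top of the list); ties are broken
#' by gene id ascending so rankings are deterministic.
#'
#' @param values Named numeric vector of differential expression over the
#'   landmark genes.
#' @return Tibble with `rank` and `gene_id`, a permutation of the input
#'   gene universe.
#' @export
#' @examples
#' rank_profile(c(g1 = 2.0, g2 = -1.0, g3 = 0.5))
rank_profile <- function(values) {
  if (is.null(names(values))) abort("`values` must be named by gene id")
  if (any(!is.finite(values))) abort("`values` contains non-finite entries")
  ord <- order(-values, names(values), method = "radix")
  tibble(rank = seq_along(values), gene_id = names(values)[ord])
}

#' Connectivity-Map style enrichment score
#'
#' Kolmogorov-Smirnov statistic for the positions of a gene set in a ranked
#' list: with the set's positions \eqn{p_{(1)} < \dots < p_{(t)}} in a list
#' of length n, \eqn{a = \max_j (j/t - p_{(j)}/n)} and \eqn{b = \max_j
#' (p_{(j)}/n - (j-1)/t)}; the score is `a` if `a > b`, else `-b`. Positive
#' scores mean the set concentrates at the top of the list, negative at the
#' bottom; the score lies in `[-1, 1]`.
#'
#' @param ranked A ranked profile from [rank_profile()] (or a character
#'   vector of gene ids in rank order).
#' @param gene_set Non-empty character vector of gene ids, all present in
#'   the ranking.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, gene_set) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty")
  pos <- match(gene_set, ids)
  if (anyNA(pos)) abort("`gene_set` contains genes absent from the ranking")
  pos <- sort(pos)
  n <- length(ids)
  t <- length(pos)
  j <- seq_len(t)
  a <- max(j / t - pos / n)
  b <- max(pos / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Reverse gene expression score of one profile
#'
#' RGES contrasts the enrichment of the disease up- and down-regulated
#' gene sets in a drug-induced ranking: `rges = es_up - es_down` when the
#' two enrichment scores have opposite signs, else 0 (the same-sign zeroing
#' rule of the Connectivity-Map scoring). A strongly negative RGES means
#' the drug pushes disease-up genes to the bottom of its ranking and
#' disease-down genes to the top, i.e. reverses the disease signature.
#'
#' @param ranked A ranked profile from [rank_profile()].
#' @param signature A `disease_signature` tibble (needs `gene_id`,
#'   `direction`).
#' @return One-row tibble with `es_up`, `es_down`, `rges` (in `[-2, 2]`).
#' @export
compute_rges <- function(ranked, signature) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  up <- intersect(signature$gene_id[signature$direction == "up"], ids)
  down <- intersect(signature$gene_id[signature$direction == "down"], ids)
  if (length(up) == 0) abort("up-regulated signature set is empty in this universe")
  if (length(down) == 0) abort("down-regulated signature set is empty in this universe")
  es_up <- enrichment_score(ids, up)
  es_down <- enrichment_score(ids, down)
  rges <- if (sign(es_up) != sign(es_down)) es_up - es_down else 0
  tibble(es_up = es_up, es_down = es_down, rges = rges)
}

#' Score all gold profiles against a disease signature
#'
#' Ranks each gold profile and computes its RGES; non-gold profiles are
#' excluded (the quality filter), and compounds left with no gold profile
#' are dropped with a warning.
#'
#' @param profiles A `drug_profiles` object.
#' @param signature A `disease_signature`.
#' @param gold_only Drop non-gold profiles first (default TRUE).
#' @return Tibble with one row per scored profile: profile metadata plus
#'   `es_up`, `es_down`, `rges`.
#' @export
score_profiles <- function(profiles, signature, gold_only = TRUE) {
  meta <- profiles$meta
  if (gold_only) {
    dropped <- setdiff(meta$compound, meta$compound[meta$is_gold])
    if (length(dropped) > 0) {
      warn(sprintf("excluding %d compound(s) with no gold profile", length(dropped)))
    }
    meta <- filter(meta, .data$is_gold)
  }
  if (nrow(meta) == 0) abort("no profiles to score after the gold filter")
  scores <- map(meta$profile_id, function(pid) {
    compute_rges(rank_profile(profiles$values[, pid]), signature)
  })
  bind_cols(meta, bind_rows(scores))
}

#' Summarize RGES into one sRGES per compound
#'
#' Profiles taken away from the reference condition (10 uM, 24 h) are put
#' on the reference scale before averaging: global condition offsets
#' `dose_offset = mean(rges | dose < ref) - mean(rges | dose >= ref)` and
#' `duration_offset` (likewise for duration) are estimated within compounds
#' that carry both conditions and averaged across them; each non-reference
#' record is adjusted by subtracting the applicable offsets, and sRGES is
#' the mean adjusted RGES over the compound's profiles. When every profile
#' of a compound sits at the reference condition, sRGES is simply the mean
#' of its RGES values.
#'
#' @param records Profile-level tibble from [score_profiles()].
#' @param ref_dose,ref_duration Reference condition (uM, hours).
#' @param dose_offset,duration_offset Optional fixed offsets; estimated
#'   from `records` when NULL.
#' @return Tibble with `compound`, `srges`, `n_profiles`,
#'   `conditions_used`, sorted ascending by `srges` (strongest reversers
#'   first).
#' @export
summarize_rges <- function(records, ref_dose = 10, ref_duration = 24,
                           dose_offset = NULL, duration_offset = NULL) {
  stopifnot(nrow(records) >= 1)
  dose_offset <- dose_offset %||%
    estimate_offset(records, records$dose_um < ref_dose)
  duration_offset <- duration_offset %||%
    estimate_offset(records, records$duration_h < ref_duration)

  records |>
    mutate(adjusted = .data$rges -
             if_else(.data$dose_um < ref_dose, dose_offset, 0) -
             if_else(.data$duration_h < ref_duration, duration_offset, 0)) |>
    group_by(.data$compound) |>
    summarise(
      srges = mean(.data$adjusted),
      n_profiles = n(),
      conditions_used = paste0(
        sum(.data$dose_um >= ref_dose & .data$duration_h >= ref_duration),
        " reference / ", n(), " total"
      ),
      .groups = "drop"
    ) |>
    arrange(.data$srges)
}

# Mean within-compound contrast between the off- and on-reference side of
# one condition, averaged over compounds observed on both sides.
estimate_offset <- function(records, is_low) {
  d <- records |>
    mutate(.low = is_low) |>
    group_by(.data$compound) |>
    filter(any(.data$.low) && any(!.data$.low)) |>
    summarise(delta = mean(.data$rges[.data$.low]) -
                mean(.data$rges[!.data$.low]), .groups = "drop")
  if (nrow(d) == 0) 0 else mean(d$delta)
}

#' Direct similarity between a disease signature and a profile
#'
#' Spearman and Pearson correlation plus cosine similarity between the
#' signature's combined log2 fold-changes and a profile's differential
#' expression, over the shared gene index — the simple alternative to
#' KS-based reversal scoring.
#'
#' @param signature_fc Named numeric vector of per-gene log2 fold-changes.
#' @param profile_values Named numeric vector of profile values.
#' @return One-row tibble with `spearman`, `pearson`, `cosine`, `n_genes`.
#'   Correlations are `NA` (with a warning) when either vector is constant;
#'   the cosine is still returned.
#' @export
similarity_metrics <- function(signature_fc, profile_values) {
  shared <- intersect(names(signature_fc), names(profile_values))
  if (length(shared) < 3) abort("need >= 3 shared genes")
  x <- signature_fc[shared]
  y <- profile_values[shared]
  cosine <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: correlation undefined, returning NA")
    return(tibble(spearman = NA_real_, pearson = NA_real_,
                  cosine = cosine, n_genes = length(shared)))
  }
  tibble(
    spearman = cor(x, y, method = "spearman"),
    pearson = cor(x, y, method = "pearson"),
    cosine = cosine,
    n_genes = length(shared)
  )
}

#' Contrast RGES across profiling conditions
#'
#' Rank-based two-group comparison of profile-level RGES values: low vs
#' high dose (< 10 vs >= 10 uM), short vs long duration (< 24 vs >= 24 h),
#' or per-compound RGES standard deviation across cell lines vs across
#' same-cell-line replicates. An exact Wilcoxon rank-sum test is used where
#' possible, the normal approximation otherwise.
#'
#' @param records Profile-level tibble from [score_profiles()].
#' @param factor One of `"dose"`, `"duration"`, `"cell_line_sd"`.
#' @param ref_dose,ref_duration Dichotomization thresholds.
#' @return One-row tibble with `factor`, `group_low`, `group_high`,
#'   `n_low`, `n_high`, `mean_low`, `mean_high`, `statistic`, `p_value`.
#' @export
condition_contrast <- function(records,
                               factor = c("dose", "duration", "cell_line_sd"),
                               ref_dose = 10, ref_duration = 24) {
  factor <- match.arg(factor)
  if (factor == "dose") {
    x <- records$rges[records$dose_um < ref_dose]
    y <- records$rges[records$dose_um >= ref_dose]
    labs <- c(sprintf("dose < %g uM", ref_dose), sprintf("dose >= %g uM", ref_dose))
  } else if (factor == "duration") {
    x <- records$rges[records$duration_h < ref_duration]
    y <- records$rges[records$duration_h >= ref_duration]
    labs <- c(sprintf("duration < %g h", ref_duration),
              sprintf("duration >= %g h", ref_duration))
  } else {
    sds <- records |>
      group_by(.data$compound) |>
      summarise(
        across_lines = stats::sd(tapply(.data$rges, .data$cell_line, mean)),
        within_line = mean(tapply(.data$rges, .data$cell_line, stats::sd),
                           na.rm = TRUE),
        .groups = "drop"
      )
    x <- sds$across_lines[is.finite(sds$across_lines)]
    y <- sds$within_line[is.finite(sds$within_line)]
    labs <- c("sd across cell lines", "sd across replicates")
  }
  if (length(x) < 2 || length(y) < 2) {
    abort(sprintf("each level of `%s` needs >= 2 observations", factor))
  }
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble(
    factor = factor, group_low = labs[1], group_high = labs[2],
    n_low = length(x), n_high = length(y),
    mean_low = mean(x), mean_high = mean(y),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}
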