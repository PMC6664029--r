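#' Collapse probe-level expression to gene level
#'
#' When several probes map to one gene, the probe with the largest
#' interquartile range (IQR) across samples is retained as that gene's
#' expression row. Exact IQR ties are broken by the lexicographically
#' smallest probe id. Probes absent from the map are dropped (a message
#' reports the count).
#'
#' @param matrix Numeric probes x samples matrix with probe-id rownames,
#'   log2 scale.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`.
#' @return Genes x samples matrix with gene-id rownames, sorted by gene id.
#' @export
collapse_probes <- function(matrix, probe_map) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || ncol(matrix) == 0) {
    abort("`matrix` must be a non-empty probes x samples matrix")
  }
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  mapped <- rownames(matrix) %in% probe_map$probe_id
  if (!all(mapped)) {
    inform(sprintf("dropping %d unmapped probe(s)", sum(!mapped)))
    matrix <- matrix[mapped, , drop = FALSE]
    if (nrow(matrix) == 0) abort("no mapped probes remain")
  }
  iqr <- apply(matrix, 1, IQR)
  keep <- tibble(probe_id = rownames(matrix), iqr = iqr) |>
    inner_join(probe_map, by = "probe_id") |>
    arrange(.data$gene_id, desc(.data$iqr), .data$probe_id) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  out <- matrix[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  out
}

#' Restrict studies to their common gene set
#'
#' Only genes present on all platforms enter the meta-analysis. Every
#' returned matrix shares an identical, alphabetically sorted gene index.
#'
#' @param matrices List of gene-level matrices with gene-id rownames.
#' @return List of matrices restricted to the sorted common gene set.
#' @export
intersect_genes <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) abort("no genes shared across all studies")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Per-study moderated t-statistics
#'
#' Two-sample (tumor vs normal) differential expression with
#' empirical-Bayes variance moderation: the pooled per-gene variance
#' \eqn{s_g^2} is shrunk toward a prior \eqn{s_0^2} with prior degrees of
#' freedom \eqn{d_0}, \eqn{\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2) /
#' (d_0 + d_g)}, and \eqn{t = \mathrm{log2fc} / \sqrt{\tilde{s}^2 (1/n_1 +
#' 1/n_2)}} is referred to a t distribution on \eqn{d_g + d_0} degrees of
#' freedom. The prior \eqn{(d_0, s_0^2)} is estimated by the method of
#' moments on \eqn{\log s_g^2} across genes (trigamma inversion); set
#' `prior_df = 0` for the ordinary pooled t or `prior_df = Inf` for full
#' shrinkage to \eqn{s_0^2}.
#'
#' @param study An `expression_study`, or a gene-level matrix.
#' @param group Tumor/normal labels per column; taken from the study's
#'   labels when `study` is an `expression_study`.
#' @param prior_df Optional fixed prior degrees of freedom.
#' @return Tibble with one row per row of the input matrix: `gene_id`,
#'   `log2fc` (mean tumor minus mean normal), `s2` (pooled variance),
#'   `s2_post` (moderated variance), `t_mod`, `df_total`, `p`, and `v`
#'   (moderated sampling variance of `log2fc`).
#' @export
moderated_t <- function(study, group = NULL, prior_df = NULL) {
  if (inherits(study, "expression_study")) {
    m <- collapse_probes(study$matrix, study$probe_map)
    group <- study$labels$group
  } else {
    m <- study
    if (is.null(group)) abort("`group` is required for a bare matrix")
  }
  if (!all(group %in% c("tumor", "normal"))) {
    abort("`group` must contain only \"tumor\" and \"normal\"")
  }
  n1 <- sum(group == "tumor")
  n2 <- sum(group == "normal")
  if (n1 < 2 || n2 < 2) abort("need >= 2 samples per group")
  if (any(!is.finite(m))) abort("expression matrix contains non-finite values")

  t_m <- m[, group == "tumor", drop = FALSE]
  n_m <- m[, group == "normal", drop = FALSE]
  mean1 <- rowMeans(t_m)
  mean2 <- rowMeans(n_m)
  log2fc <- mean1 - mean2
  ss1 <- rowSums((t_m - mean1)^2)
  ss2 <- rowSums((n_m - mean2)^2)
  df_g <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df_g
  if (all(s2 <= 0)) abort("degenerate input: zero within-group variance everywhere")

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2[s2 > 0], df_g)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s02 = NA_real_)
  } else if (is.infinite(prior_df)) {
    prior <- list(d0 = Inf, s02 = exp(mean(log(s2[s2 > 0]))))
  } else {
    prior <- list(d0 = prior_df,
                  s02 = fit_variance_prior(s2[s2 > 0], df_g)$s02)
  }

  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s02, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s02 + df_g * s2) / (prior$d0 + df_g)
  }
  v <- s2_post * (1 / n1 + 1 / n2)
  t_mod <- log2fc / sqrt(v)
  df_total <- df_g + prior$d0
  p <- if (is.infinite(df_total)) {
    2 * pnorm(-abs(t_mod))
  } else {
    2 * pt(-abs(t_mod), df = df_total)
  }
  tibble(
    gene_id = rownames(m), log2fc = unname(log2fc), s2 = unname(s2),
    s2_post = unname(s2_post), t_mod = unname(t_mod), df_total = df_total,
    p = unname(p), v = unname(v)
  )
}

# Method-of-moments prior for the variance distribution: on z = log(s2),
# E[z] and Var[z] are digamma/trigamma expressions in (d0, s02); solving the
# variance equation needs a trigamma inverse (Newton iteration).
fit_variance_prior <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(e)
  evar <- sum((e - mean(e))^2) / (n - 1) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Fixed-effect meta-analysis of per-study effects
#'
#' Inverse-variance-weighted pooling: weights \eqn{w_i = 1/v_i}, combined
#' effect \eqn{\sum w_i \mathrm{fc}_i / \sum w_i}, combined variance
#' \eqn{1/\sum w_i}, with z and a two-sided p from the normal reference
#' and BH-adjusted q-values across genes.
#'
#' @param stats_per_study List of per-study tibbles from [moderated_t()];
#'   all must share the same gene index (use [intersect_genes()] upstream).
#' @return Tibble with `gene_id`, `combined_log2fc`, `combined_v`, `z`,
#'   `p_meta`, `q`.
#' @export
fixed_effect_meta <- function(stats_per_study) {
  stopifnot(length(stats_per_study) >= 1)
  ids <- stats_per_study[[1]]$gene_id
  for (s in stats_per_study) {
    if (!identical(s$gene_id, ids)) abort("studies do not share a gene index")
    if (any(s$v <= 0)) abort("non-positive sampling variance v")
  }
  fc <- vapply(stats_per_study, function(s) s$log2fc, numeric(length(ids)))
  v <- vapply(stats_per_study, function(s) s$v, numeric(length(ids)))
  fc <- matrix(fc, nrow = length(ids))
  v <- matrix(v, nrow = length(ids))
  w <- 1 / v
  combined_v <- 1 / rowSums(w)
  combined_fc <- rowSums(w * fc) * combined_v
  z <- combined_fc / sqrt(combined_v)
  p_meta <- 2 * pnorm(-abs(z))
  tibble(
    gene_id = ids, combined_log2fc = combined_fc, combined_v = combined_v,
    z = z, p_meta = p_meta, q = bh_adjust(p_meta)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement), returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Select the disease signature from meta-analysis results
#'
#' Up-regulated genes satisfy `q < q_threshold` and `combined_log2fc >
#' fc_threshold`; down-regulated genes mirror this with `< -fc_threshold`.
#' The defaults are the study thresholds (adjusted P < 0.001, |log2FC| >
#' 1.5). Genes are ordered by decreasing |combined_log2fc|.
#'
#' @param meta Tibble from [fixed_effect_meta()].
#' @param q_threshold Adjusted-p cutoff.
#' @param fc_threshold log2 fold-change cutoff (applied as > for up, < -
#'   for down).
#' @return A `disease_signature` tibble: `gene_id`, `direction`,
#'   `combined_log2fc`, `p_meta`, `q`.
#' @export
select_degs <- function(meta, q_threshold = 0.001, fc_threshold = 1.5) {
  stopifnot(q_threshold > 0, fc_threshold > 0)
  sig <- meta |>
    filter(.data$q < q_threshold, abs(.data$combined_log2fc) > fc_threshold) |>
    mutate(direction = if_else(.data$combined_log2fc > 0, "up", "down")) |>
    arrange(desc(abs(.data$combined_log2fc))) |>
    select("gene_id", "direction", "combined_log2fc", "p_meta", "q")
  class(sig) <- c("disease_signature", class(sig))
  sig
}

#' Fit the full disease meta-signature
#'
#' One-call wrapper over the meta-signature stage: probe collapsing per
#' study, restriction to the common gene set, per-study moderated t,
#' fixed-effect meta-analysis with BH adjustment, and DEG selection.
#'
#' @param studies List of `expression_study` objects.
#' @param q_threshold,fc_threshold Signature thresholds, see
#'   [select_degs()].
#' @param prior_df Optional fixed moderation prior df, see [moderated_t()].
#' @return Object of class `meta_signature`: list with `meta` (per-gene
#'   meta statistics), `signature` (the `disease_signature`), `per_study`
#'   (list of per-study statistics), `n_genes`, and the thresholds.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 120, n_deg_up = 8, n_deg_down = 6,
#'                          n_studies = 2,
#'                          samples_per_study = cbind(n_tumor = c(8, 8),
#'                                                    n_normal = c(10, 10)),
#'                          seed = 42)
#' fit <- meta_signature(simulate_disease_studies(cfg))
#' glance(fit)
meta_signature <- function(studies, q_threshold = 0.001, fc_threshold = 1.5,
                           prior_df = NULL) {
  stopifnot(length(studies) >= 1)
  mats <- lapply(studies, function(s) collapse_probes(s$matrix, s$probe_map))
  mats <- intersect_genes(mats)
  per_study <- map2(mats, studies, function(m, s) {
    moderated_t(m, group = s$labels$group, prior_df = prior_df)
  })
  meta <- fixed_effect_meta(per_study)
  sig <- select_degs(meta, q_threshold, fc_threshold)
  structure(
    list(meta = meta, signature = sig, per_study = per_study,
         n_genes = nrow(meta), q_threshold = q_threshold,
         fc_threshold = fc_threshold),
    class = "meta_signature"
  )
}

#' @export
print.meta_signature <- function(x, ...) {
  cat(sprintf("<meta_signature> %d genes across %d studies\n",
              x$n_genes, length(x$per_study)))
  cat(sprintf("  signature: %d up / %d down (q < %g, |log2FC| > %g)\n",
              sum(x$signature$direction == "up"),
              sum(x$signature$direction == "down"),
              x$q_threshold, x$fc_threshold))
  invisible(x)
}

#' @rdname meta_signature
#' @param x A `meta_signature` object.
#' @param ... Unused.
#' @method tidy meta_signature
#' @export
tidy.meta_signature <- function(x, ...) {
  x$meta |>
    mutate(in_signature = .data$gene_id %in% x$signature$gene_id)
}

#' @rdname meta_signature
#' @method glance meta_signature
#' @export
glance.meta_signature <- function(x, ...) {
  tibble(
    n_genes = x$n_genes,
    n_studies = length(x$per_study),
    n_up = sum(x$signature$direction == "up"),
    n_down = sum(x$signature$direction == "down"),
    q_threshold = x$q_threshold,
    fc_threshold = x$fc_threshold
  )
}
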