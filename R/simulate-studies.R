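#' Generate synthetic tumor/normal expression studies
#'
#' Emulates a multi-platform microarray compendium: each study carries a
#' probe-level log2 expression matrix, tumor/normal sample labels, a
#' distinct platform id, and a probe-to-gene map in which at least 10% of
#' genes are measured by two probes (so probe collapsing is exercised).
#' Planted DEGs are shifted by `deg_log2fc` in tumors, in a consistent
#' direction across studies; background genes are i.i.d. Gaussian noise
#' around per-gene baseline means on the log2 scale.
#'
#' @param config A [simulation_config()].
#' @param truth A `ground_truth`, normally from [simulate_ground_truth()]
#'   with the same config.
#' @return List of `expression_study` objects, one per study. Each has
#'   elements `matrix` (probes x samples, log2 scale), `labels` (tibble with
#'   `sample_id`, `group`), `platform_id` and `probe_map` (tibble with
#'   `probe_id`, `gene_id`).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 60, n_deg_up = 5, n_deg_down = 4,
#'                          samples_per_study = NULL, seed = 7)
#' studies <- simulate_disease_studies(cfg)
#' dim(studies[[1]]$matrix)
simulate_disease_studies <- function(config = simulation_config(),
                                     truth = simulate_ground_truth(config)) {
  validate_simulation_config(config)
  if (length(truth$genes) != config$n_genes) {
    abort("`truth` and `config` disagree on n_genes")
  }
  set.seed(derive_seed(config$seed, "studies"))

  genes <- truth$genes
  effect <- setNames(rep(0, config$n_genes), genes)
  effect[truth$planted_up_genes] <- config$deg_log2fc
  effect[truth$planted_down_genes] <- -config$deg_log2fc

  lapply(seq_len(config$n_studies), function(s) {
    n1 <- config$samples_per_study[s, "n_tumor"]
    n2 <- config$samples_per_study[s, "n_normal"]

    # >= 10% of genes get a second probe on this platform
    n_dup <- max(1L, ceiling(0.12 * config$n_genes))
    dup_genes <- sample(genes, n_dup)
    probe_map <- tibble(
      gene_id = c(genes, dup_genes)
    ) |>
      arrange(.data$gene_id) |>
      mutate(probe_id = sprintf("S%dP%04d", s, row_number())) |>
      select("probe_id", "gene_id")

    sample_ids <- c(sprintf("S%d_T%02d", s, seq_len(n1)),
                    sprintf("S%d_N%02d", s, seq_len(n2)))
    group <- c(rep("tumor", n1), rep("normal", n2))

    affinity <- rnorm(nrow(probe_map), sd = 0.3)  # probe-specific offset
    base <- truth$gene_means[probe_map$gene_id] + affinity
    shift <- effect[probe_map$gene_id]
    m <- matrix(rnorm(nrow(probe_map) * (n1 + n2)), nrow = nrow(probe_map))
    m <- m + base
    m[, group == "tumor"] <- m[, group == "tumor"] + shift
    dimnames(m) <- list(probe_map$probe_id, sample_ids)

    structure(
      list(
        matrix = m,
        labels = tibble(sample_id = sample_ids, group = group),
        platform_id = sprintf("SIMPL%d", s),
        probe_map = probe_map
      ),
      class = "expression_study"
    )
  })
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d probes x %d samples (%d tumor / %d normal)\n",
              x$platform_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$labels$group == "tumor"), sum(x$labels$group == "normal")))
  invisible(x)
}

#' Generate synthetic cell-line expression profiles
#'
#' Cell-line log2 expression shares the per-gene baseline means of the
#' tumor compendium plus line-specific noise, so tumor samples and cell
#' lines are positively correlated over the shared gene universe (as real
#' tumors are with lineage-matched cell lines).
#'
#' @param config A [simulation_config()].
#' @param truth Matching `ground_truth`.
#' @param n_lines Number of cell lines.
#' @return Genes x lines numeric matrix, log2 scale.
#' @export
simulate_cellline_expression <- function(config = simulation_config(),
                                         truth = simulate_ground_truth(config),
                                         n_lines = 8L) {
  set.seed(derive_seed(config$seed, "misc"))
  m <- matrix(rnorm(config$n_genes * n_lines), nrow = config$n_genes)
  m <- m + truth$gene_means
  dimnames(m) <- list(truth$genes, sprintf("LINE%02d", seq_len(n_lines)))
  m
}
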