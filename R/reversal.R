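#' Normalized rank positions of signature genes in compound rankings
#'
#' Each compound's gold profiles are reduced to one ranking by taking the
#' per-gene median differential value, ranking descending (rank 1 = most
#' up-regulated, ties by gene id), and normalizing: position = rank / n,
#' so positions lie in (0, 1] with small values at the top of the list.
#'
#' @param profiles A `drug_profiles` object.
#' @param signature A `disease_signature` (needs `gene_id`, `direction`).
#' @return Tibble with one row per (signature gene, compound):
#'   `gene_id`, `direction`, `compound`, `position`.
#' @export
normalized_rank_positions <- function(profiles, signature) {
  universe <- rownames(profiles$values)
  missing <- setdiff(signature$gene_id, universe)
  if (length(missing) > 0) {
    abort(paste0("signature gene(s) missing from the landmark universe: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  meta <- filter(profiles$meta, .data$is_gold)
  if (nrow(meta) == 0) abort("no gold profiles")
  n <- length(universe)
  compounds <- unique(meta$compound)

  pos_list <- map(compounds, function(cpd) {
    cols <- meta$profile_id[meta$compound == cpd]
    v <- if (length(cols) == 1) {
      profiles$values[, cols]
    } else {
      apply(profiles$values[, cols, drop = FALSE], 1, median)
    }
    ord <- order(-v, universe, method = "radix")
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    pos[match(signature$gene_id, universe)] / n
  })
  tibble(
    gene_id = rep(signature$gene_id, times = length(compounds)),
    direction = rep(signature$direction, times = length(compounds)),
    compound = rep(compounds, each = nrow(signature)),
    position = unlist(pos_list)
  )
}

#' One-sided rank test for reversal of one gene
#'
#' For an up-regulated disease gene, reversal means active compounds rank
#' it lower (closer to the bottom, larger normalized position) than
#' inactive compounds; for a down-regulated gene, higher (smaller
#' position). The Wilcoxon rank-sum test is evaluated one-sided in the
#' reversing direction (exact when sample sizes permit and there are no
#' ties).
#'
#' @param positions_active,positions_inactive Normalized positions of the
#'   gene under active / inactive compounds (each length >= 2).
#' @param direction `"up"` or `"down"`.
#' @return One-sided p-value.
#' @export
test_reversal <- function(positions_active, positions_inactive,
                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(positions_active) < 2 || length(positions_inactive) < 2) {
    abort("need >= 2 compounds per activity group")
  }
  alt <- if (direction == "up") "greater" else "less"
  suppressWarnings(
    wilcox.test(positions_active, positions_inactive,
                alternative = alt)$p.value
  )
}

#' Leave-one-compound-out reversal-gene screen
#'
#' For every held-out compound, each signature gene's one-sided reversal
#' p-value is recomputed on the remaining compounds and BH-adjusted across
#' genes within the trial. A gene is called reversed only when its adjusted
#' p stays below `q_threshold` in every trial and its rank shift points in
#' the reversing direction in every trial. Inside the trials a vectorized
#' normal-approximation rank-sum test (tie-corrected, with continuity
#' correction) is used.
#'
#' @param table Position table from [normalized_rank_positions()].
#' @param classes Activity classes (tibble with `compound`, `label`),
#'   e.g. from [activity_classes()]. At least 3 compounds per class.
#' @param q_threshold Per-trial adjusted-p cutoff (default 0.25).
#' @return Object of class `reversal_screen`: list with `results` (tibble
#'   `gene_id`, `direction`, `worst_q`, `reversed`), `q_matrix` (genes x
#'   trials), `n_trials`, `q_threshold`. Supports [tidy()] and [glance()].
#' @export
loco_reversal_genes <- function(table, classes, q_threshold = 0.25) {
  d <- inner_join(table, select(classes, "compound", "label"),
                  by = "compound")
  compounds <- unique(d$compound)
  labels <- classes$label[match(compounds, classes$compound)]
  if (sum(labels == "active") < 3 || sum(labels == "inactive") < 3) {
    abort("need >= 3 active and >= 3 inactive compounds")
  }
  genes <- distinct(table, .data$gene_id, .data$direction)
  P <- matrix(NA_real_, nrow = nrow(genes), ncol = length(compounds),
              dimnames = list(genes$gene_id, compounds))
  P[cbind(match(d$gene_id, genes$gene_id), match(d$compound, compounds))] <-
    d$position
  if (anyNA(P)) abort("position table is not one row per gene-compound pair")
  is_up <- genes$direction == "up"

  q_mat <- matrix(NA_real_, nrow = nrow(genes), ncol = length(compounds),
                  dimnames = list(genes$gene_id, compounds))
  shift_ok <- matrix(NA, nrow = nrow(genes), ncol = length(compounds))
  for (k in seq_along(compounds)) {
    sub <- P[, -k, drop = FALSE]
    lab <- labels[-k]
    p <- ranksum_p_rows(sub, lab == "active", is_up)
    q_mat[, k] <- bh_adjust(p)
    dshift <- rowMeans(sub[, lab == "active", drop = FALSE]) -
      rowMeans(sub[, lab == "inactive", drop = FALSE])
    shift_ok[, k] <- ifelse(is_up, dshift > 0, dshift < 0)
  }

  results <- genes |>
    mutate(
      worst_q = apply(q_mat, 1, max),
      consistent_shift = apply(shift_ok, 1, all),
      reversed = .data$worst_q < q_threshold & .data$consistent_shift
    ) |>
    arrange(.data$worst_q)
  structure(
    list(results = results, q_matrix = q_mat,
         n_trials = length(compounds), q_threshold = q_threshold),
    class = "reversal_screen"
  )
}

# Row-wise one-sided Mann-Whitney p-values by normal approximation with tie
# correction and continuity correction. `greater` rows test active > rest.
ranksum_p_rows <- function(mat, is_active, is_up) {
  n1 <- sum(is_active)
  n2 <- sum(!is_active)
  N <- n1 + n2
  R <- t(apply(mat, 1, rank))
  W <- rowSums(R[, is_active, drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- apply(mat, 1, function(x) {
    if (anyDuplicated(x) == 0) return(0)
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  })
  sigma2 <- n1 * n2 / 12 * ((N + 1) - ties / (N * (N - 1)))
  sigma <- sqrt(pmax(sigma2, .Machine$double.eps))
  p_greater <- pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
  p_less <- pnorm((U - mu + 0.5) / sigma)
  ifelse(is_up, p_greater, p_less)
}

#' @export
print.reversal_screen <- function(x, ...) {
  cat(sprintf("<reversal_screen> %d genes x %d LOCO trials (q < %g)\n",
              nrow(x$results), x$n_trials, x$q_threshold))
  cat(sprintf("  reversal genes called: %d\n", sum(x$results$reversed)))
  invisible(x)
}

#' @rdname loco_reversal_genes
#' @param x A `reversal_screen` object.
#' @param ... Unused.
#' @method tidy reversal_screen
#' @export
tidy.reversal_screen <- function(x, ...) {
  x$results
}

#' @rdname loco_reversal_genes
#' @method glance reversal_screen
#' @export
glance.reversal_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    n_trials = x$n_trials,
    n_reversed = sum(x$results$reversed),
    q_threshold = x$q_threshold
  )
}
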