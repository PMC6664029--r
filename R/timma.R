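#' Map sRGES to a bounded sensitivity
#'
#' The target-inhibition model works on drug sensitivities in `[0, 1]`;
#' sRGES values are mapped by min-max rescaling so the strongest reverser
#' (lowest sRGES) gets sensitivity 1 and the weakest gets 0. The mapping
#' is monotone decreasing in sRGES.
#'
#' @param srges Named numeric vector of per-drug sRGES (>= 2 distinct
#'   values).
#' @return Named numeric vector of sensitivities in `[0, 1]`.
#' @export
#' @examples
#' rges_to_sensitivity(c(a = -2, b = 0, c = 2))
rges_to_sensitivity <- function(srges) {
  if (is.null(names(srges))) abort("`srges` must be named by drug")
  rng <- range(srges)
  if (rng[1] == rng[2]) abort("constant sRGES: sensitivity scaling undefined")
  (rng[2] - srges) / (rng[2] - rng[1])
}

#' Target-inhibition sensitivity prediction (maximization/minimization averaging)
#'
#' Predicts the sensitivity of inhibiting a target set `T` from observed
#' single-drug sensitivities, assuming sensitivity is monotone in the
#' inhibited set: a lower bound `L` is the maximum sensitivity over drugs
#' whose target set is contained in `T` (0 if none), an upper bound `U` is
#' the minimum over drugs whose target set contains `T` (1 if none). Drugs
#' whose target set equals `T` fix the prediction at the mean of their
#' sensitivities; otherwise the prediction averages the bounds,
#' `(L + U) / 2`.
#'
#' @param target_set Character vector of target ids (may be empty).
#' @param matrix Binary drugs x targets matrix with dimnames; every drug
#'   needs at least one target.
#' @param y Named numeric vector of per-drug sensitivities in `[0, 1]`.
#' @return Predicted sensitivity in `[0, 1]`.
#' @export
timma_predict <- function(target_set, matrix, y) {
  check_drug_targets(matrix, y)
  unknown <- setdiff(target_set, colnames(matrix))
  if (length(unknown) > 0) {
    abort(paste0("unknown target id(s): ", paste(unknown, collapse = ", ")))
  }
  ind <- as.integer(colnames(matrix) %in% target_set)
  y <- y[rownames(matrix)]
  subset_of_T <- matrix %*% (1 - ind) == 0   # drug targets all inside T
  superset_of_T <- (1 - matrix) %*% ind == 0 # drug covers all of T
  exact <- subset_of_T & superset_of_T
  if (any(exact)) return(mean(y[exact]))
  L <- if (any(subset_of_T)) max(y[subset_of_T]) else 0
  U <- if (any(superset_of_T)) min(y[superset_of_T]) else 1
  (L + U) / 2
}

check_drug_targets <- function(matrix, y) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort("drug-target matrix needs drug rownames and target colnames")
  }
  if (!all(matrix %in% c(0, 1))) abort("drug-target matrix must be binary")
  if (any(rowSums(matrix) < 1)) abort("every drug needs >= 1 target")
  if (!all(rownames(matrix) %in% names(y))) {
    abort("`y` must name a sensitivity for every drug")
  }
  if (any(y < 0 | y > 1)) abort("sensitivities must lie in [0, 1]")
  invisible(TRUE)
}

#' Synergy scores of a target pair
#'
#' Deviation of the combined sensitivity from three reference models:
#' additive `S_a = y_ij - (y_i + y_j)`, multiplicative
#' `S_m = y_ij - y_i * y_j`, and highest single agent
#' `S_l = y_ij - max(y_i, y_j)`.
#'
#' @param y_i,y_j,y_ij Sensitivities in `[0, 1]` (single targets and the
#'   pair).
#' @return One-row tibble with `s_a`, `s_m`, `s_l`.
#' @export
synergy_scores <- function(y_i, y_j, y_ij) {
  vals <- c(y_i, y_j, y_ij)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
    abort("sensitivities must lie in [0, 1]")
  }
  tibble(
    s_a = y_ij - (y_i + y_j),
    s_m = y_ij - y_i * y_j,
    s_l = y_ij - max(y_i, y_j)
  )
}

# Per-target-pair scores for a drug pair: i ranges over targets of d1, j
# over targets of d2, i == j pairs are skipped; y(i), y(j), y(i,j) are
# model predictions for the singleton and pair target sets.
synergy_pair_table <- function(d1, d2, matrix, y) {
  t1 <- colnames(matrix)[matrix[d1, ] == 1]
  t2 <- colnames(matrix)[matrix[d2, ] == 1]
  pairs <- tidyr::crossing(target_i = t1, target_j = t2) |>
    filter(.data$target_i != .data$target_j)
  if (nrow(pairs) == 0) {
    abort("no valid target pairs (identical single-target drugs)",
          class = "revsig_no_pairs")
  }
  singles <- unique(c(t1, t2))
  y_single <- setNames(
    map_dbl(singles, function(t) timma_predict(t, matrix, y)), singles
  )
  pairs$y_i <- unname(y_single[pairs$target_i])
  pairs$y_j <- unname(y_single[pairs$target_j])
  pairs$y_ij <- purrr::map2_dbl(pairs$target_i, pairs$target_j,
                                function(a, b) timma_predict(c(a, b), matrix, y))
  pairs$s_a <- pairs$y_ij - (pairs$y_i + pairs$y_j)
  pairs$s_m <- pairs$y_ij - pairs$y_i * pairs$y_j
  pairs$s_l <- pairs$y_ij - pmax(pairs$y_i, pairs$y_j)
  pairs
}

#' Average synergy score of a drug pair
#'
#' The chosen synergy score is evaluated for every (target of drug 1,
#' target of drug 2) pair — skipping shared targets — with the single- and
#' pair-target sensitivities predicted by [timma_predict()], and averaged
#' over the pairs.
#'
#' @param d1,d2 Drug ids (rownames of `matrix`).
#' @param matrix Binary drugs x targets matrix.
#' @param y Named per-drug sensitivities in `[0, 1]`.
#' @param score_kind `"additive"`, `"multiplicative"` or
#'   `"highest-agent"`.
#' @return Average synergy score (scalar).
#' @export
average_synergy <- function(d1, d2, matrix, y,
                            score_kind = c("additive", "multiplicative",
                                           "highest-agent")) {
  score_kind <- match.arg(score_kind)
  check_pair(d1, d2, matrix)
  tab <- synergy_pair_table(d1, d2, matrix, y)
  col <- c(additive = "s_a", multiplicative = "s_m",
           `highest-agent` = "s_l")[[score_kind]]
  mean(tab[[col]])
}

check_pair <- function(d1, d2, matrix) {
  missing <- setdiff(c(d1, d2), rownames(matrix))
  if (length(missing) > 0) {
    abort(paste0("drug(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Predicted sensitivity of a drug combination
#'
#' `sensitivity = expectation + synergy`: the expectation is the
#' target-inhibition prediction for the union of the two drugs' target
#' sets (or, with `expectation_kind = "independence"`, the Bliss-style
#' null `1 - (1 - y1)(1 - y2)`), the synergy term is [average_synergy()],
#' and the sum is clipped to `[0, 1]`.
#'
#' @inheritParams average_synergy
#' @param expectation_kind `"timma"` (union target set, default) or
#'   `"independence"`.
#' @return One-row tibble with `drug1`, `drug2`, mean per-pair scores
#'   `s_a`, `s_m`, `s_l`, `average_synergy` (the chosen kind),
#'   `expectation`, `predicted_sensitivity`.
#' @export
combination_sensitivity <- function(d1, d2, matrix, y,
                                    score_kind = c("additive",
                                                   "multiplicative",
                                                   "highest-agent"),
                                    expectation_kind = c("timma",
                                                         "independence")) {
  score_kind <- match.arg(score_kind)
  expectation_kind <- match.arg(expectation_kind)
  check_drug_targets(matrix, y)
  check_pair(d1, d2, matrix)
  tab <- synergy_pair_table(d1, d2, matrix, y)
  col <- c(additive = "s_a", multiplicative = "s_m",
           `highest-agent` = "s_l")[[score_kind]]
  syn <- mean(tab[[col]])
  expectation <- if (expectation_kind == "timma") {
    union_set <- colnames(matrix)[matrix[d1, ] == 1 | matrix[d2, ] == 1]
    timma_predict(union_set, matrix, y)
  } else {
    1 - (1 - y[[d1]]) * (1 - y[[d2]])
  }
  tibble(
    drug1 = d1, drug2 = d2,
    s_a = mean(tab$s_a), s_m = mean(tab$s_m), s_l = mean(tab$s_l),
    average_synergy = syn, expectation = expectation,
    predicted_sensitivity = clip01(expectation + syn)
  )
}

#' Screen all drug pairs for combination sensitivity
#'
#' Evaluates [combination_sensitivity()] for every unordered pair of the
#' supplied drugs and ranks pairs by predicted sensitivity (descending).
#' Pairs of identical single-target drugs (no valid target pair) are
#' skipped.
#'
#' @inheritParams combination_sensitivity
#' @param drugs Drugs to screen; defaults to all rows of `matrix`.
#' @return Object of class `synergy_screen`: list with `pairs` (ranked
#'   tibble), `score_kind`, `n_drugs`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
synergy_screen <- function(matrix, y, drugs = rownames(matrix),
                           score_kind = c("additive", "multiplicative",
                                          "highest-agent"),
                           expectation_kind = c("timma", "independence")) {
  score_kind <- match.arg(score_kind)
  expectation_kind <- match.arg(expectation_kind)
  check_drug_targets(matrix, y)
  stopifnot(length(drugs) >= 2, all(drugs %in% rownames(matrix)))
  combos <- utils::combn(drugs, 2, simplify = FALSE)
  rows <- map(combos, function(pr) {
    tryCatch(
      combination_sensitivity(pr[1], pr[2], matrix, y, score_kind,
                              expectation_kind),
      revsig_no_pairs = function(e) NULL
    )
  })
  pairs <- bind_rows(rows) |>
    arrange(desc(.data$predicted_sensitivity))
  structure(
    list(pairs = pairs, score_kind = score_kind, n_drugs = length(drugs)),
    class = "synergy_screen"
  )
}

#' @export
print.synergy_screen <- function(x, ...) {
  cat(sprintf("<synergy_screen> %d drugs, %d pairs (%s synergy)\n",
              x$n_drugs, nrow(x$pairs), x$score_kind))
  print(head(x$pairs, 5))
  invisible(x)
}

#' @rdname synergy_screen
#' @param x A `synergy_screen` object.
#' @param ... Unused.
#' @method tidy synergy_screen
#' @export
tidy.synergy_screen <- function(x, ...) {
  x$pairs
}

#' @rdname synergy_screen
#' @method glance synergy_screen
#' @export
glance.synergy_screen <- function(x, ...) {
  tibble(
    n_drugs = x$n_drugs,
    n_pairs = nrow(x$pairs),
    score_kind = x$score_kind,
    top_sensitivity = if (nrow(x$pairs) > 0) x$pairs$predicted_sensitivity[1]
                      else NA_real_
  )
}
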