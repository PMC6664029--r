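#' Generate the planted ground truth for a synthetic cohort
#'
#' Draws every latent quantity the downstream recovery tests need: the
#' planted up-/down-regulated DEG sets, per-gene baseline means, the set of
#' reverser compounds with per-compound reversal strengths, the planted
#' reversal score feeding the IC50 link, noiseless median IC50s, and the
#' binary drug-target matrix together with positive target weights that
#' define a monotone true combination-sensitivity function.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ground_truth` with elements `genes`,
#'   `planted_up_genes`, `planted_down_genes`, `gene_means`, `compounds`,
#'   `reverser_compounds`, `reversal_u`, `planted_rges`, `true_ic50`,
#'   `drug_targets` (binary compounds x targets matrix) and
#'   `target_weights`.
#' @seealso [true_sensitivity()] for the monotone combination truth.
#' @export
simulate_ground_truth <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, "truth"))

  genes <- landmark_genes(config$n_genes)
  planted <- sample(genes, config$n_deg_up + config$n_deg_down)
  up <- sort(planted[seq_len(config$n_deg_up)])
  down <- sort(setdiff(planted, up))
  gene_means <- setNames(rnorm(config$n_genes, mean = 7, sd = 1), genes)

  compounds <- sprintf("CPD%03d", seq_len(config$n_compounds))
  n_rev <- round(config$frac_reversers * config$n_compounds)
  reversers <- sort(sample(compounds, n_rev))
  # Per-compound strength multiplier grades the reversers; non-reversers
  # carry no planted signal at all.
  u <- setNames(runif(config$n_compounds, min = 0.65, max = 1), compounds)
  planted_rges <- setNames(rep(0, config$n_compounds), compounds)
  planted_rges[reversers] <- -1.9 * config$reversal_strength * u[reversers]

  # IC50 link: log10(IC50) = a + b * planted score, with a/b placed so the
  # reverser population straddles the 10 uM activity threshold.
  true_ic50 <- 10^(ic50_link_intercept + ic50_link_slope * planted_rges)

  set.seed(derive_seed(config$seed, "targets"))
  targets <- sprintf("T%02d", seq_len(config$n_targets))
  dt <- matrix(0L, nrow = config$n_compounds, ncol = config$n_targets,
               dimnames = list(compounds, targets))
  for (i in seq_len(config$n_compounds)) {
    k <- sample(1:min(3L, config$n_targets), 1L)
    dt[i, sample(config$n_targets, k)] <- 1L
  }
  target_weights <- setNames(runif(config$n_targets, 0.1, 0.8), targets)

  structure(
    list(
      genes = genes,
      planted_up_genes = up,
      planted_down_genes = down,
      gene_means = gene_means,
      compounds = compounds,
      reverser_compounds = reversers,
      reversal_u = u,
      planted_rges = planted_rges,
      true_ic50 = true_ic50,
      drug_targets = dt,
      target_weights = target_weights
    ),
    class = "ground_truth"
  )
}

# Placement of the log-linear IC50 link (log10-uM scale).
ic50_link_intercept <- 2.25
ic50_link_slope <- 1.4

#' True sensitivity of a target-inhibition set
#'
#' The planted combination truth is monotone in the inhibited target set by
#' construction: `f(T) = 1 - exp(-sum of target weights in T)`, so supersets
#' are never less sensitive. This is the oracle the target-inhibition model
#' is checked against.
#'
#' @param truth A `ground_truth` object.
#' @param target_set Character vector of target ids (may be empty).
#' @return Sensitivity in `[0, 1)`.
#' @export
true_sensitivity <- function(truth, target_set) {
  stopifnot(inherits(truth, "ground_truth"))
  unknown <- setdiff(target_set, names(truth$target_weights))
  if (length(unknown) > 0) {
    abort(paste0("unknown target id(s): ", paste(unknown, collapse = ", ")))
  }
  1 - exp(-sum(truth$target_weights[unique(target_set)]))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d genes (%d up / %d down planted)\n", length(x$genes),
              length(x$planted_up_genes), length(x$planted_down_genes)))
  cat(sprintf("  %d compounds (%d reversers), %d targets\n",
              length(x$compounds), length(x$reverser_compounds),
              ncol(x$drug_targets)))
  invisible(x)
}
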