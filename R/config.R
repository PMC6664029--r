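#' Simulation configuration
#'
#' Parameters for the synthetic cohort that emulates the statistical
#' structure of the real study inputs: a multi-study tumor/normal
#' expression compendium with planted differentially expressed genes
#' (DEGs), drug-induced landmark-gene profiles in which a subset of
#' compounds reverses the disease signature, IC50 activity records
#' anti-correlated with reversal strength, and a binary drug-target
#' matrix with a monotone combination-sensitivity truth.
#'
#' Defaults mirror the real cohort dimensions: 978 landmark genes, four
#' studies totalling 64 tumors and 114 normal or benign samples (178
#' samples), 53 up- and 42 down-regulated planted DEGs, and 172 profiled
#' compounds. Doses must include the 10 uM reference concentration and
#' durations the 24 h reference treatment time.
#'
#' @param n_genes Number of landmark genes.
#' @param n_studies Number of expression studies.
#' @param samples_per_study Two-column matrix (or NULL) with one row per
#'   study and columns `n_tumor`, `n_normal`. Defaults to a proportional
#'   allocation of 64 tumors / 114 normals across `n_studies`.
#' @param n_deg_up,n_deg_down Planted up-/down-regulated DEG counts.
#' @param deg_log2fc Planted effect size in log2 units.
#' @param n_compounds Number of profiled compounds.
#' @param frac_reversers Fraction of compounds that truly reverse the
#'   disease signature.
#' @param reversal_strength Reversal effect size in `[0, 1]`; 1 pushes the
#'   planted DEGs to the extremes of a reverser's profile ranking.
#' @param ic50_noise_sd Noise SD of the IC50 link, log10-uM units.
#' @param doses Profiled concentrations in uM; must contain 10.
#' @param durations Profiled treatment durations in hours; must contain 24.
#' @param n_targets Number of targets in the drug-target matrix.
#' @param seed Root seed; every generator derives its own substream.
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$samples_per_study
simulation_config <- function(n_genes = 978L,
                              n_studies = 4L,
                              samples_per_study = NULL,
                              n_deg_up = 53L,
                              n_deg_down = 42L,
                              deg_log2fc = 2.0,
                              n_compounds = 172L,
                              frac_reversers = 0.3,
                              reversal_strength = 0.8,
                              ic50_noise_sd = 0.3,
                              doses = c(5, 10),
                              durations = c(6, 24),
                              n_targets = 20L,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_studies = as.integer(n_studies),
    samples_per_study = samples_per_study,
    n_deg_up = as.integer(n_deg_up), n_deg_down = as.integer(n_deg_down),
    deg_log2fc = deg_log2fc, n_compounds = as.integer(n_compounds),
    frac_reversers = frac_reversers, reversal_strength = reversal_strength,
    ic50_noise_sd = ic50_noise_sd, doses = doses, durations = durations,
    n_targets = as.integer(n_targets), seed = as.integer(seed)
  )
  if (is.null(cfg$samples_per_study)) {
    cfg$samples_per_study <- allocate_samples(64L, 114L, cfg$n_studies)
  }
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

# Proportional split of the tumor/normal totals across studies, largest
# remainders first so the totals are preserved exactly.
allocate_samples <- function(n_tumor, n_normal, n_studies) {
  split1 <- function(total, k) {
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    as.integer(base)
  }
  m <- cbind(n_tumor = split1(n_tumor, n_studies),
             n_normal = split1(n_normal, n_studies))
  rownames(m) <- sprintf("study%d", seq_len(n_studies))
  m
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_genes", "n_studies", "n_deg_up", "n_deg_down",
              "n_compounds", "n_targets")
  for (f in counts) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] <= 0) {
      abort_field(f, "must be a positive count")
    }
  }
  if (!is_scalar_number(cfg$frac_reversers) ||
      cfg$frac_reversers < 0 || cfg$frac_reversers > 1) {
    abort_field("frac_reversers", "must lie in [0, 1]")
  }
  if (!is_scalar_number(cfg$reversal_strength) ||
      cfg$reversal_strength < 0 || cfg$reversal_strength > 1) {
    abort_field("reversal_strength", "must lie in [0, 1]")
  }
  if (!is_scalar_number(cfg$ic50_noise_sd) || cfg$ic50_noise_sd < 0) {
    abort_field("ic50_noise_sd", "must be a non-negative number")
  }
  if (!is_scalar_number(cfg$deg_log2fc) || cfg$deg_log2fc < 0) {
    abort_field("deg_log2fc", "must be a non-negative number")
  }
  if (!(10 %in% cfg$doses)) {
    abort_field("doses", "must include the 10 uM reference concentration")
  }
  if (!(24 %in% cfg$durations)) {
    abort_field("durations", "must include the 24 h reference duration")
  }
  if (cfg$n_deg_up + cfg$n_deg_down >= cfg$n_genes) {
    abort_field("n_deg_up", "n_deg_up + n_deg_down must be < n_genes")
  }
  sps <- cfg$samples_per_study
  if (!is.matrix(sps) || nrow(sps) != cfg$n_studies || ncol(sps) != 2L ||
      any(sps < 2L)) {
    abort_field("samples_per_study",
                "must be an n_studies x 2 matrix with >= 2 samples per group")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d landmark genes, %d studies (%d tumors / %d normals)\n",
              x$n_genes, x$n_studies,
              sum(x$samples_per_study[, "n_tumor"]),
              sum(x$samples_per_study[, "n_normal"])))
  cat(sprintf("  planted DEGs: %d up / %d down at log2FC %.2f\n",
              x$n_deg_up, x$n_deg_down, x$deg_log2fc))
  cat(sprintf("  %d compounds (%.0f%% reversers, strength %.2f), %d targets, seed %d\n",
              x$n_compounds, 100 * x$frac_reversers, x$reversal_strength,
              x$n_targets, x$seed))
  invisible(x)
}
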