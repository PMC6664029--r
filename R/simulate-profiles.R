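#' Generate drug-induced landmark-gene profiles
#'
#' Emulates L1000-style differential-expression profiles. Every compound is
#' profiled under several conditions (replicates at the 10 uM / 24 h
#' reference, a second cell line, a lower dose and a shorter duration).
#' Reverser compounds have the planted up-regulated disease genes pushed
#' toward the bottom of their ranking and the planted down-regulated genes
#' toward the top, with a larger shift at the reference condition
#' (dose >= 10 uM and duration >= 24 h); non-reversers are exchangeable
#' noise. A minority of profiles is flagged non-gold and must be excluded
#' before scoring; the first reference profile of each compound is always
#' gold so every compound remains scoreable.
#'
#' @param config A [simulation_config()].
#' @param truth Matching `ground_truth`.
#' @return A `drug_profiles` object: list with `values` (genes x profiles
#'   matrix of differential expression) and `meta` (tibble with
#'   `profile_id`, `compound`, `cell_line`, `dose_um`, `duration_h`,
#'   `is_gold`).
#' @export
simulate_compound_profiles <- function(config = simulation_config(),
                                       truth = simulate_ground_truth(config)) {
  validate_simulation_config(config)
  if (length(truth$genes) != config$n_genes) {
    abort("`truth` and `config` disagree on n_genes")
  }
  set.seed(derive_seed(config$seed, "profiles"))

  low_dose <- if (any(config$doses < 10)) max(config$doses[config$doses < 10]) else 10
  short_dur <- if (any(config$durations < 24)) max(config$durations[config$durations < 24]) else 24

  cond <- tibble(
    cell_line = c("PC3", "PC3", "VCAP", "PC3", "PC3"),
    dose_um = c(10, 10, 10, low_dose, 10),
    duration_h = c(24, 24, 24, 24, short_dur)
  )
  meta <- tidyr::crossing(compound = truth$compounds, idx = seq_len(nrow(cond))) |>
    arrange(.data$compound, .data$idx) |>
    bind_cols(cond[rep(seq_len(nrow(cond)), length(truth$compounds)), ]) |>
    mutate(profile_id = sprintf("%s_P%d", .data$compound, .data$idx),
           is_gold = .data$idx == 1L | runif(n()) < 0.9) |>
    select("profile_id", "compound", "cell_line", "dose_um", "duration_h",
           "is_gold")

  values <- matrix(rnorm(config$n_genes * nrow(meta)), nrow = config$n_genes,
                   dimnames = list(truth$genes, meta$profile_id))

  # Reversal planting: shift amplitude scales with the global strength and
  # the per-compound grade; off-reference conditions see a weaker shift and
  # each (compound, cell line) carries a shared multiplier so variation
  # across cell lines exceeds replicate noise.
  amp <- 6 * config$reversal_strength * truth$reversal_u
  is_rev <- meta$compound %in% truth$reverser_compounds
  cond_mult <- ifelse(meta$dose_um >= 10 & meta$duration_h >= 24, 1, 0.6)
  cl_key <- paste(meta$compound, meta$cell_line)
  cl_mult <- setNames(pmin(1.2, pmax(0.8, rnorm(length(unique(cl_key)), 1, 0.1))),
                      unique(cl_key))
  shift <- amp[meta$compound] * cond_mult * cl_mult[cl_key] * is_rev

  up <- truth$planted_up_genes
  down <- truth$planted_down_genes
  values[up, ] <- values[up, ] - rep(shift, each = length(up))
  values[down, ] <- values[down, ] + rep(shift, each = length(down))

  structure(list(values = values, meta = meta), class = "drug_profiles")
}

#' @export
print.drug_profiles <- function(x, ...) {
  cat(sprintf("<drug_profiles> %d genes x %d profiles (%d compounds, %d gold)\n",
              nrow(x$values), ncol(x$values),
              dplyr::n_distinct(x$meta$compound), sum(x$meta$is_gold)))
  invisible(x)
}

#' @method as_tibble drug_profiles
#' @export
as_tibble.drug_profiles <- function(x, ...) {
  as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "profile_id",
                        values_to = "value") |>
    left_join(x$meta, by = "profile_id")
}

#' Generate compound activity records
#'
#' Per-compound, per-cell-line IC50 (uM) or AUC records with a log-linear
#' link to the compound's reversal score: `log10(IC50) = a + b * score +
#' noise`, so strong reversers get low IC50s and the reverser population
#' straddles the 10 uM activity threshold. IC50s are strictly positive by
#' construction (noise is added on the log10 scale). AUC uses a bounded
#' linear link on `[0, 1]` (lower AUC = more sensitive).
#'
#' @param config A [simulation_config()].
#' @param truth Matching `ground_truth`.
#' @param scores Optional named per-compound reversal scores used by the
#'   link; defaults to the planted scores in `truth`. Supplying computed
#'   sRGES values here yields an activity set exactly monotone in them,
#'   which is how the noise-free recovery property is exercised.
#' @param measure `"IC50"` (default) or `"AUC"`.
#' @param cell_lines Cell lines to emit one record for per compound.
#' @return Tibble with `compound`, `cell_line`, `measure`, `value`.
#' @export
simulate_activity <- function(config = simulation_config(),
                              truth = simulate_ground_truth(config),
                              scores = NULL,
                              measure = c("IC50", "AUC"),
                              cell_lines = c("PC3", "VCAP")) {
  validate_simulation_config(config)
  measure <- match.arg(measure)
  scores <- scores %||% truth$planted_rges
  if (is.null(names(scores)) || !all(truth$compounds %in% names(scores))) {
    abort("`scores` must be named and cover every compound in `truth`")
  }
  set.seed(derive_seed(config$seed, "activity"))

  rec <- tidyr::crossing(compound = truth$compounds, cell_line = cell_lines) |>
    mutate(measure = measure)
  eps <- rnorm(nrow(rec), sd = config$ic50_noise_sd)
  s <- unname(scores[rec$compound])
  if (measure == "IC50") {
    rec$value <- 10^(ic50_link_intercept + ic50_link_slope * s + eps)
  } else {
    rec$value <- clip01(0.85 + 0.3 * s + 0.3 * eps)
  }
  rec
}

#' Generate a reversal-gene screening scenario
#'
#' A focused generator for the reversal-gene discovery stage: a disease
#' signature, one gold reference profile per compound, and an
#' active/inactive activity classification in which a small set of planted
#' reversal genes shifts its normalized rank position between the groups.
#' For a planted up-regulated reversal gene the expression value in active
#' compounds is shifted by `-m` with `m = sqrt(2) * qnorm(0.5 + shift)`,
#' which moves its expected normalized position from 0.5 to `0.5 + shift`
#' in a standard-normal background (down-genes mirror this).
#'
#' @param n_genes Landmark universe size.
#' @param n_sig_up,n_sig_down Signature sizes (up/down).
#' @param n_reversal Number of planted reversal genes (split between
#'   directions).
#' @param shift Planted normalized-rank shift in `(0, 0.5)`.
#' @param n_active,n_inactive Compound counts per activity class.
#' @param seed Integer seed.
#' @return List with `signature` (a `disease_signature` tibble), `profiles`
#'   (a `drug_profiles` object), `classes` (tibble with `compound`,
#'   `median_value`, `label`) and `truth` (planted reversal gene ids by
#'   direction).
#' @export
simulate_reversal_screen <- function(n_genes = 978L, n_sig_up = 53L,
                                     n_sig_down = 42L, n_reversal = 4L,
                                     shift = 0.3, n_active = 50L,
                                     n_inactive = 48L, seed = 1L) {
  stopifnot(shift > 0, shift < 0.5, n_reversal <= n_sig_up + n_sig_down)
  set.seed(derive_seed(seed, "reversal"))

  genes <- landmark_genes(n_genes)
  sig_genes <- sample(genes, n_sig_up + n_sig_down)
  up <- sort(sig_genes[seq_len(n_sig_up)])
  down <- sort(setdiff(sig_genes, up))
  n_rev_up <- ceiling(n_reversal / 2)
  rev_up <- sample(up, n_rev_up)
  rev_down <- sample(down, n_reversal - n_rev_up)

  signature <- tibble(
    gene_id = c(up, down),
    direction = c(rep("up", n_sig_up), rep("down", n_sig_down)),
    combined_log2fc = c(runif(n_sig_up, 1.6, 3), runif(n_sig_down, -3, -1.6)),
    p_meta = runif(n_sig_up + n_sig_down, 0, 1e-5),
    q = runif(n_sig_up + n_sig_down, 0, 5e-4)
  )
  class(signature) <- c("disease_signature", class(signature))

  compounds <- sprintf("RCPD%03d", seq_len(n_active + n_inactive))
  active <- compounds[seq_len(n_active)]
  m <- sqrt(2) * qnorm(0.5 + shift)
  values <- matrix(rnorm(n_genes * length(compounds)), nrow = n_genes,
                   dimnames = list(genes, paste0(compounds, "_P1")))
  act_cols <- paste0(active, "_P1")
  values[rev_up, act_cols] <- values[rev_up, act_cols] - m
  values[rev_down, act_cols] <- values[rev_down, act_cols] + m

  meta <- tibble(
    profile_id = colnames(values), compound = compounds,
    cell_line = "PC3", dose_um = 10, duration_h = 24, is_gold = TRUE
  )
  profiles <- structure(list(values = values, meta = meta),
                        class = "drug_profiles")
  classes <- tibble(
    compound = compounds,
    median_value = c(runif(n_active, 0.5, 9.5), runif(n_inactive, 10.5, 80)),
    label = c(rep("active", n_active), rep("inactive", n_inactive))
  )
  list(signature = signature, profiles = profiles, classes = classes,
       truth = list(reversal_up = sort(rev_up), reversal_down = sort(rev_down)))
}
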