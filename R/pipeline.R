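#' Run the full drug-repositioning pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> meta-signature -> RGES -> sRGES -> activity ->
#' reversal genes -> synergy with one configuration. Every stage writes its
#' output TSVs under `out_dir`; a manifest and a JSON run report (summary
#' counts plus a full parameter echo) are written last. All randomness
#' flows from `config$seed` through named per-stage substreams, so a fixed
#' seed reproduces every file bit for bit. A stage failure aborts with the
#' stage name and cause and leaves a `FAILED_<stage>` marker file next to
#' the partial outputs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @param q_deg,lfc Disease-signature thresholds (adjusted p and |log2FC|).
#' @param ic50_threshold Activity threshold in uM.
#' @param q_reversal LOCO reversal-gene adjusted-p threshold.
#' @param score_kind Synergy score kind, see [average_synergy()].
#' @param top_n_synergy Number of top compounds (by sRGES) entering the
#'   combination screen.
#' @param write_inputs Also write the simulated input TSVs (default TRUE).
#' @param input_dir Optional directory of user-supplied inputs written in
#'   the package's TSV layouts (study triplets, `profiles.tsv` +
#'   `profile_meta.tsv`, `activity.tsv`, `drug_targets.tsv`). When given,
#'   the simulate stage is replaced by a load stage and no ground truth is
#'   involved; the cell-line similarity output is skipped unless the
#'   directory also holds `celllines.tsv` (gene_id + one column per line).
#' @return A `run_report` object (invisibly a list): `stages` tibble,
#'   `counts`, `params`, `files`.
#' @export
#' @examples
#' \donttest{
#' cfg <- simulation_config(seed = 1)
#' report <- run_pipeline(cfg, out_dir = tempfile("pipeline"))
#' report$counts$n_deg_up
#' }
run_pipeline <- function(config = simulation_config(),
                         out_dir,
                         input_dir = NULL,
                         q_deg = 0.001, lfc = 1.5,
                         ic50_threshold = 10, q_reversal = 0.25,
                         score_kind = c("additive", "multiplicative",
                                        "highest-agent"),
                         top_n_synergy = 40,
                         write_inputs = TRUE) {
  score_kind <- match.arg(score_kind)
  validate_simulation_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, paste0("FAILED_", name)))
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
    stages <<- c(stages, name)
    message(sprintf("[revsig] stage %-10s done", name))
    res
  }

  # 1. simulate (or load user inputs) ---------------------------------------
  sim <- if (!is.null(input_dir)) {
    run_stage("load", {
      expr_files <- list.files(input_dir, pattern = "_expression\\.tsv$")
      if (length(expr_files) == 0) {
        abort(paste0("no *_expression.tsv study files in ", input_dir))
      }
      studies <- lapply(sub("_expression\\.tsv$", "", expr_files),
                        function(px) read_study_tsv(input_dir, px))
      pf <- file.path(input_dir, "profiles.tsv")
      if (!file.exists(pf)) abort(paste0("profile file not found: ", pf))
      profiles <- read_profiles_tsv(input_dir)
      cl_path <- file.path(input_dir, "celllines.tsv")
      celllines <- if (file.exists(cl_path)) {
        d <- readr::read_tsv(cl_path, show_col_types = FALSE)
        m <- as.matrix(d[, -1]); rownames(m) <- d$gene_id; m
      } else NULL
      list(truth = NULL, studies = studies, profiles = profiles,
           activity = NULL, celllines = celllines)
    })
  } else {
    run_stage("simulate", {
    truth <- simulate_ground_truth(config)
    studies <- simulate_disease_studies(config, truth)
    profiles <- simulate_compound_profiles(config, truth)
    activity <- simulate_activity(config, truth)
    celllines <- simulate_cellline_expression(config, truth)
    if (write_inputs) {
      in_dir <- file.path(out_dir, "inputs")
      walk(studies, function(s) write_study_tsv(s, in_dir))
      write_profiles_tsv(profiles, in_dir)
      readr::write_tsv(activity, file.path(in_dir, "activity.tsv"))
      write_drug_targets_tsv(truth$drug_targets,
                             file.path(in_dir, "drug_targets.tsv"))
    }
    list(truth = truth, studies = studies, profiles = profiles,
         activity = activity, celllines = celllines)
    })
  }

  # 2. meta-signature -------------------------------------------------------
  fit <- run_stage("meta-de", {
    fit <- meta_signature(sim$studies, q_threshold = q_deg,
                          fc_threshold = lfc)
    readr::write_tsv(fit$meta, file.path(out_dir, "meta_stats.tsv"))
    readr::write_tsv(fit$signature, file.path(out_dir, "signature.tsv"))
    fit
  })

  # 3. RGES per profile -----------------------------------------------------
  rges <- run_stage("rges", {
    r <- score_profiles(sim$profiles, fit$signature, gold_only = TRUE)
    readr::write_tsv(r, file.path(out_dir, "rges.tsv"))
    r
  })

  # 4. sRGES per compound ---------------------------------------------------
  srges <- run_stage("srges", {
    s <- summarize_rges(rges)
    readr::write_tsv(s, file.path(out_dir, "srges.tsv"))
    s
  })

  # 5. activity integration -------------------------------------------------
  act <- run_stage("activity", {
    activity <- sim$activity
    if (is.null(activity)) {
      af <- file.path(input_dir, "activity.tsv")
      if (!file.exists(af)) abort(paste0("activity file not found: ", af))
      activity <- readr::read_tsv(af, show_col_types = FALSE)
    }
    classes <- activity_classes(activity, threshold = ic50_threshold)
    agg <- aggregate_activity(activity)
    potency <- evaluate_reversal_potency(srges, agg)
    readr::write_tsv(classes, file.path(out_dir, "activity_class.tsv"))
    readr::write_tsv(potency, file.path(out_dir, "potency_eval.tsv"))
    if (!is.null(sim$celllines)) {
      tumor <- collapse_probes(sim$studies[[1]]$matrix,
                               sim$studies[[1]]$probe_map)
      sim_expr <- expression_similarity(tumor, sim$celllines,
                                        top_k = min(5000, nrow(tumor)))
      readr::write_tsv(sim_expr,
                       file.path(out_dir, "expression_similarity.tsv"))
    }
    list(classes = classes, potency = potency)
  })

  # 6. reversal genes -------------------------------------------------------
  rev <- run_stage("reversal", {
    positions <- normalized_rank_positions(sim$profiles, fit$signature)
    screen <- loco_reversal_genes(positions, act$classes,
                                  q_threshold = q_reversal)
    readr::write_tsv(screen$results, file.path(out_dir, "reversal_genes.tsv"))
    readr::write_tsv(as_tibble(screen$q_matrix, rownames = "gene_id"),
                     file.path(out_dir, "reversal_q_matrix.tsv"))
    screen
  })

  # 7. synergy --------------------------------------------------------------
  syn <- run_stage("synergy", {
    top <- head(srges$compound, min(top_n_synergy, nrow(srges)))
    dt <- if (is.null(sim$truth)) {
      read_drug_targets_tsv(file.path(input_dir, "drug_targets.tsv"))
    } else {
      sim$truth$drug_targets
    }
    top <- intersect(top, rownames(dt))
    y <- rges_to_sensitivity(setNames(srges$srges, srges$compound))
    y <- y[intersect(names(y), rownames(dt))]
    screen <- synergy_screen(dt, y, drugs = sort(top),
                             score_kind = score_kind)
    readr::write_tsv(screen$pairs, file.path(out_dir, "synergy.tsv"))
    sq <- screen$pairs |>
      select("drug1", "drug2", "predicted_sensitivity") |>
      tidyr::pivot_wider(names_from = "drug2",
                         values_from = "predicted_sensitivity")
    readr::write_tsv(sq, file.path(out_dir, "synergy_matrix.tsv"))
    screen
  })

  report <- structure(
    list(
      stages = tibble(stage = stages, status = "complete"),
      counts = list(
        n_genes = fit$n_genes,
        n_deg_up = sum(fit$signature$direction == "up"),
        n_deg_down = sum(fit$signature$direction == "down"),
        n_profiles_scored = nrow(rges),
        n_compounds_scored = nrow(srges),
        n_active = sum(act$classes$label == "active"),
        n_inactive = sum(act$classes$label == "inactive"),
        potency_rho = act$potency$rho,
        n_reversal_genes = sum(rev$results$reversed),
        n_synergy_pairs = nrow(syn$pairs),
        top_synergy_pair = if (nrow(syn$pairs) > 0) {
          paste(syn$pairs$drug1[1], syn$pairs$drug2[1], sep = "+")
        } else NA_character_,
        top_predicted_sensitivity = if (nrow(syn$pairs) > 0) {
          syn$pairs$predicted_sensitivity[1]
        } else NA_real_
      ),
      params = list(
        seed = config$seed, q_deg = q_deg, lfc = lfc,
        ic50_threshold = ic50_threshold, q_reversal = q_reversal,
        score_kind = score_kind, top_n_synergy = top_n_synergy,
        reference_dose_um = 10, reference_duration_h = 24,
        config = unclass(config)[setdiff(names(config), "samples_per_study")]
      ),
      files = sort(setdiff(list.files(out_dir, recursive = TRUE),
                           "report.json"))
    ),
    class = "run_report"
  )
  jsonlite::write_json(report[c("counts", "params", "files")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(tibble(file = report$files),
                   file.path(out_dir, "manifest.tsv"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  stages complete: %s\n", paste(x$stages$stage, collapse = ", ")))
  cat(sprintf("  signature: %d up / %d down; %d compounds scored (%d active / %d inactive)\n",
              x$counts$n_deg_up, x$counts$n_deg_down,
              x$counts$n_compounds_scored, x$counts$n_active,
              x$counts$n_inactive))
  cat(sprintf("  potency rho = %.3f; %d reversal genes; top pair %s (%.3f)\n",
              x$counts$potency_rho, x$counts$n_reversal_genes,
              x$counts$top_synergy_pair, x$counts$top_predicted_sensitivity))
  invisible(x)
}
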