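# Plain-TSV readers and writers for every pipeline artifact. Column layouts
# are stable and documented here rather than per function: expression rows
# are probes (first column `probe_id`), profile tables are genes x profiles
# (first column `gene_id`), everything else is tidy one-row-per-record.

#' Write one expression study to TSV files
#'
#' Writes `<prefix>_expression.tsv` (first column `probe_id`, one column
#' per sample), `<prefix>_labels.tsv` (`sample_id`, `group`) and
#' `<prefix>_probe_map.tsv` (`probe_id`, `gene_id`).
#'
#' @param study An `expression_study`.
#' @param dir Output directory (created if missing).
#' @param prefix File prefix, e.g. the platform id.
#' @return Invisibly, the paths written.
#' @export
write_study_tsv <- function(study, dir, prefix = study$platform_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_expression.tsv", "_labels.tsv",
                                           "_probe_map.tsv")))
  expr <- as_tibble(study$matrix, rownames = "probe_id")
  readr::write_tsv(expr, paths[1])
  readr::write_tsv(study$labels, paths[2])
  readr::write_tsv(study$probe_map, paths[3])
  invisible(paths)
}

#' Read one expression study from TSV files
#'
#' Counterpart of [write_study_tsv()].
#'
#' @param dir Directory holding the three files.
#' @param prefix File prefix used at write time.
#' @return An `expression_study`.
#' @export
read_study_tsv <- function(dir, prefix) {
  expr <- readr::read_tsv(file.path(dir, paste0(prefix, "_expression.tsv")),
                          show_col_types = FALSE)
  m <- as.matrix(expr[, -1])
  rownames(m) <- expr$probe_id
  structure(
    list(
      matrix = m,
      labels = readr::read_tsv(file.path(dir, paste0(prefix, "_labels.tsv")),
                               show_col_types = FALSE),
      platform_id = prefix,
      probe_map = readr::read_tsv(
        file.path(dir, paste0(prefix, "_probe_map.tsv")),
        show_col_types = FALSE
      )
    ),
    class = "expression_study"
  )
}

#' Write drug profiles to TSV files
#'
#' Writes `profiles.tsv` (`gene_id` + one column per profile) and
#' `profile_meta.tsv` (`profile_id`, `compound`, `cell_line`, `dose_um`,
#' `duration_h`, `is_gold`).
#'
#' @param profiles A `drug_profiles` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_profiles_tsv <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("profiles.tsv", "profile_meta.tsv"))
  readr::write_tsv(as_tibble(profiles$values, rownames = "gene_id"), paths[1])
  readr::write_tsv(profiles$meta, paths[2])
  invisible(paths)
}

#' Read drug profiles from TSV files
#'
#' Counterpart of [write_profiles_tsv()].
#'
#' @param dir Directory holding `profiles.tsv` and `profile_meta.tsv`.
#' @return A `drug_profiles` object.
#' @export
read_profiles_tsv <- function(dir) {
  vals <- readr::read_tsv(file.path(dir, "profiles.tsv"),
                          show_col_types = FALSE)
  m <- as.matrix(vals[, -1])
  rownames(m) <- vals$gene_id
  meta <- readr::read_tsv(file.path(dir, "profile_meta.tsv"),
                          show_col_types = FALSE)
  structure(list(values = m, meta = meta), class = "drug_profiles")
}

#' Write / read the drug-target matrix
#'
#' TSV with a `drug` first column and one 0/1 column per target.
#'
#' @param matrix Binary drugs x targets matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_drug_targets_tsv <- function(matrix, path) {
  readr::write_tsv(as_tibble(matrix, rownames = "drug"), path)
  invisible(path)
}

#' @rdname write_drug_targets_tsv
#' @export
read_drug_targets_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$drug
  storage.mode(m) <- "integer"
  m
}
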