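# Internal helpers shared across modules.

# Deterministic substream seeds: one root seed, one named lane per stage, so
# regenerating any single input never perturbs the others.
derive_seed <- function(seed, lane) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  lanes <- c(
    truth = 1L, studies = 2L, profiles = 3L, activity = 4L,
    targets = 5L, reversal = 6L, misc = 7L
  )
  off <- lanes[[lane]]
  (abs(as.integer(seed)) %% 1000000L) * 1009L + off * 7919L
}

abort_field <- function(field, msg) {
  abort(paste0("invalid `", field, "`: ", msg), class = "revsig_config_error")
}

clip01 <- function(x) pmin(1, pmax(0, x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Landmark gene identifiers
#'
#' Synthetic stand-ins for the L1000 landmark gene universe. All generators
#' and scoring functions in the package share this identifier scheme.
#'
#' @param n Number of landmark genes (default 978, the size of the L1000
#'   landmark set).
#' @return Character vector of gene ids, `"G0001"` ... `"G0978"` by default.
#' @export
#' @examples
#' head(landmark_genes(10))
landmark_genes <- function(n = 978L) {
  sprintf("G%04d", seq_len(n))
}
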