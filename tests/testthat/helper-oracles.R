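# Independent oracles and small fixtures shared across tests. The oracles
# deliberately use different algorithms from the package implementations.

# Brute-force BH step-up: sort, compute n*p/i, enforce monotonicity from the
# largest p downwards, map back to input order.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- (n / seq_len(n)) * p[o]
  if (n > 1) {
    for (i in (n - 1):1) {
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    }
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force KS enrichment via the running empirical-CDF difference walked
# over every list position.
bf_es <- function(ids, gene_set) {
  n <- length(ids)
  hit <- ids %in% gene_set
  t <- sum(hit)
  f_set <- cumsum(hit) / t
  i <- seq_len(n)
  a <- max(f_set - i / n)
  b <- max(i / n - c(0, f_set[-n]))
  if (a > b) a else -b
}

# Pooled two-sample t for one gene (textbook formula).
bf_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Random drug-target instance whose sensitivities come from a planted
# monotone truth f(T) = 1 - exp(-sum of weights in T).
random_monotone_instance <- function(n_targets, n_drugs, seed) {
  set.seed(seed)
  targets <- sprintf("t%02d", seq_len(n_targets))
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  m <- matrix(0L, n_drugs, n_targets, dimnames = list(drugs, targets))
  for (i in seq_len(n_drugs)) {
    m[i, sample(n_targets, sample(1:min(3, n_targets), 1))] <- 1L
  }
  w <- stats::runif(n_targets, 0.1, 0.9)
  names(w) <- targets
  f <- function(set) 1 - exp(-sum(w[set]))
  y <- apply(m, 1, function(row) f(targets[row == 1]))
  list(matrix = m, y = y, w = w, f = f, targets = targets)
}

# Exhaustive subset enumeration of timma predictions for small instances.
all_subsets <- function(targets) {
  n <- length(targets)
  lapply(seq_len(2^n) - 1L, function(code) {
    targets[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
  })
}

small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_genes = 150L, n_studies = 2L,
    samples_per_study = cbind(n_tumor = c(8L, 8L), n_normal = c(10L, 10L)),
    n_deg_up = 10L, n_deg_down = 8L, n_compounds = 24L, n_targets = 8L,
    seed = seed
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Signature over an arbitrary universe: first `n_up` ids up, next `n_down`
# down, with filler statistics.
toy_signature <- function(up, down) {
  sig <- tibble::tibble(
    gene_id = c(up, down),
    direction = c(rep("up", length(up)), rep("down", length(down))),
    combined_log2fc = c(rep(2, length(up)), rep(-2, length(down))),
    p_meta = 1e-6, q = 1e-4
  )
  class(sig) <- c("disease_signature", class(sig))
  sig
}
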