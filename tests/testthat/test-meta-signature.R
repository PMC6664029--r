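test_that("probe collapsing keeps the most variable probe per gene", {
  m <- rbind(
    A = c(0, 2, 4, 6),    # IQR 3
    B = c(1, 1.5, 2, 2.5),
    C = c(5, 5, 5, 5)
  )
  pm <- data.frame(probe_id = c("A", "B", "C"),
                   gene_id = c("g1", "g1", "g2"))
  out <- collapse_probes(m, pm)
  expect_equal(rownames(out), c("g1", "g2"))
  expect_equal(unname(out["g1", ]), unname(m["A", ]))
  # single-probe gene passes through untouched
  expect_equal(unname(out["g2", ]), unname(m["C", ]))

  # exact IQR tie: lexicographically smallest probe id wins
  m2 <- rbind(P2 = c(0, 1, 2, 3), P1 = c(3, 2, 1, 0))
  pm2 <- data.frame(probe_id = c("P1", "P2"), gene_id = c("g", "g"))
  out2 <- collapse_probes(m2, pm2)
  expect_equal(unname(out2["g", ]), unname(m2["P1", ]))

  # unmapped probes are dropped with a message; empty input errors
  expect_message(collapse_probes(rbind(m, X = 1:4), pm), "1 unmapped")
  expect_error(collapse_probes(matrix(numeric(0), 0, 0), pm), "non-empty")
  # row count equals the number of distinct mapped genes
  expect_equal(nrow(out), length(unique(pm$gene_id)))
})

test_that("gene intersection restricts to a shared sorted index", {
  m1 <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  m2 <- matrix(1:6, 3, 2, dimnames = list(c("b", "c", "d"), NULL))
  out <- intersect_genes(list(m1, m2))
  expect_equal(rownames(out[[1]]), c("b", "c"))
  expect_equal(rownames(out[[2]]), c("b", "c"))
  expect_identical(intersect_genes(list(m1))[[1]], m1)
  m3 <- matrix(1:2, 1, 2, dimnames = list("z", NULL))
  expect_error(intersect_genes(list(m1, m3)), "shared")
})

test_that("moderated t reduces to the pooled t when the prior df is zero", {
  # textbook case: {0,1,2} vs {3,4,5}
  m <- rbind(g1 = c(0, 1, 2, 3, 4, 5))
  grp <- c("tumor", "tumor", "tumor", "normal", "normal", "normal")
  s <- moderated_t(m, group = grp, prior_df = 0)
  expect_equal(s$log2fc, -3)
  expect_equal(s$s2, 1)
  expect_equal(round(s$t_mod, 3), -3.674)

  # random matrices: equality with the textbook pooled t to 1e-10
  set.seed(99)
  for (rep in 1:5) {
    mm <- matrix(rnorm(50 * 12), 50, 12,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
    grp2 <- rep(c("tumor", "normal"), each = 6)
    got <- moderated_t(mm, group = grp2, prior_df = 0)
    want <- apply(mm, 1, function(x) bf_pooled_t(x[grp2 == "tumor"],
                                                 x[grp2 == "normal"]))
    expect_equal(got$t_mod, unname(want), tolerance = 1e-10)
  }
})

test_that("infinite prior df shrinks every variance to the prior", {
  set.seed(7)
  m <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  grp <- rep(c("tumor", "normal"), each = 5)
  s <- moderated_t(m, group = grp, prior_df = Inf)
  expect_equal(length(unique(round(s$s2_post, 12))), 1)
  expect_error(moderated_t(m[, 1:3], group = grp[c(1, 2, 6)]), ">= 2 samples")
  m0 <- matrix(1, 4, 8, dimnames = list(letters[1:4], NULL))
  expect_error(moderated_t(m0, group = rep(c("tumor", "normal"), each = 4)),
               "degenerate")
})

test_that("estimated moderation prior agrees with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(123)
  m <- matrix(rnorm(200 * 14, sd = rep(sqrt(rchisq(200, 4) / 4), 14)),
              200, 14, dimnames = list(sprintf("g%03d", 1:200), NULL))
  grp <- rep(c("tumor", "normal"), each = 7)
  got <- moderated_t(m, group = grp)
  sq <- limma::squeezeVar(got$s2, df = 12)
  expect_equal(got$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("fixed-effect pooling follows inverse-variance weighting", {
  s1 <- tibble::tibble(gene_id = "g", log2fc = 1, v = 0.1)
  s2 <- tibble::tibble(gene_id = "g", log2fc = 1, v = 0.1)
  out <- fixed_effect_meta(list(s1, s2))
  expect_equal(out$combined_log2fc, 1)
  expect_equal(out$combined_v, 0.05)

  s3 <- tibble::tibble(gene_id = "g", log2fc = 2, v = 0.2)
  out2 <- fixed_effect_meta(list(s1, s3))
  expect_equal(out2$combined_log2fc, 4 / 3)
  expect_equal(out2$combined_v, 1 / 15)

  # single study: combined equals the input
  out1 <- fixed_effect_meta(list(s1))
  expect_equal(out1$combined_log2fc, s1$log2fc)
  expect_equal(out1$combined_v, s1$v)

  bad <- tibble::tibble(gene_id = "g", log2fc = 1, v = 0)
  expect_error(fixed_effect_meta(list(s1, bad)), "variance")

  # combined variance never exceeds the smallest per-study variance
  set.seed(42)
  stats <- lapply(1:3, function(i) {
    tibble::tibble(gene_id = sprintf("g%02d", 1:30), log2fc = rnorm(30),
                   v = runif(30, 0.01, 1))
  })
  res <- fixed_effect_meta(stats)
  vmin <- do.call(pmin, lapply(stats, function(s) s$v))
  expect_true(all(res$combined_v < vmin))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(1)
  for (i in 1:200) {
    p <- runif(sample(1:100, 1))
    expect_identical(bh_adjust(p), bf_bh(p))
  }
})

test_that("signature selection applies both thresholds and sorts by effect", {
  meta <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    combined_log2fc = c(1.6, 1.4, -2.5, -1.6),
    combined_v = 0.01, z = 1,
    p_meta = c(1e-5, 1e-5, 1e-5, 0.5),
    q = c(5e-4, 5e-4, 5e-4, 0.6)
  )
  sig <- select_degs(meta)
  expect_equal(sig$gene_id, c("c", "a"))  # b fails |fc|, d fails q
  expect_equal(sig$direction, c("down", "up"))
})

test_that("the meta-signature recovers the planted DEGs on a small cohort", {
  cfg <- small_config(seed = 2)
  truth <- simulate_ground_truth(cfg)
  fit <- meta_signature(simulate_disease_studies(cfg, truth))
  planted <- c(truth$planted_up_genes, truth$planted_down_genes)
  expect_gte(mean(fit$signature$gene_id %in% planted), 0.95)

  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_genes)
  gl <- glance(fit)
  expect_equal(gl$n_up + gl$n_down, nrow(fit$signature))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a null cohort stays calibrated after BH adjustment", {
  cfg <- small_config(seed = 3, deg_log2fc = 0)
  fit <- meta_signature(simulate_disease_studies(cfg))
  frac <- mean(fit$meta$q < 0.05)
  se <- sqrt(0.05 * 0.95 / fit$n_genes)
  expect_lte(frac, 0.05 + 3 * se)
})
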