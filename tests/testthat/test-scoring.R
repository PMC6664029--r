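test_that("profile ranking is descending with deterministic tie-breaks", {
  r <- rank_profile(c(g1 = 2.0, g2 = -1.0, g3 = 0.5))
  expect_equal(r$gene_id, c("g1", "g3", "g2"))
  # equal values: gene id ascending decides
  r2 <- rank_profile(c(b = 1, a = 1, c = 0))
  expect_equal(r2$gene_id, c("a", "b", "c"))
  # all equal collapses to gene-id order
  r3 <- rank_profile(c(z = 0, y = 0, x = 0))
  expect_equal(r3$gene_id, c("x", "y", "z"))
  expect_error(rank_profile(c(a = 1, b = NA)), "non-finite")
  expect_error(rank_profile(1:3), "named")
})

test_that("enrichment score reproduces hand-computed KS values", {
  ids <- paste0("g", 1:10)
  expect_equal(enrichment_score(ids, ids[1:2]), 0.8)
  expect_equal(enrichment_score(ids, ids[9:10]), -0.9)
  # saturated set: a = 0 and b = 1/n, so the score is -1/n (tends to 0)
  expect_equal(enrichment_score(ids, ids), -0.1)
  expect_error(enrichment_score(ids, character(0)), "non-empty")
  expect_error(enrichment_score(ids, "nope"), "absent")
})

test_that("enrichment score equals the running-sum oracle on random instances", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    ids <- sample(sprintf("g%03d", 1:n))
    set <- sample(ids, sample(1:min(10, n), 1))
    expect_identical(enrichment_score(ids, set), bf_es(ids, set))
  }
})

test_that("RGES composes the two enrichment scores with same-sign zeroing", {
  ids <- paste0("g", 1:10)
  # up set at the bottom (es -0.9), down set at the top (es +0.8)
  sig <- toy_signature(up = ids[9:10], down = ids[1:2])
  out <- compute_rges(ids, sig)
  expect_equal(out$es_up, -0.9)
  expect_equal(out$es_down, 0.8)
  expect_equal(out$rges, -1.7)

  # both sets near the top: same sign, score zeroed
  sig2 <- toy_signature(up = ids[1:2], down = ids[3:4])
  out2 <- compute_rges(ids, sig2)
  expect_gt(out2$es_up * out2$es_down, 0)
  expect_equal(out2$rges, 0)

  sig3 <- toy_signature(up = "absent", down = ids[1:2])
  expect_error(compute_rges(ids, sig3), "up-regulated")
})

test_that("perfect reversal and mimicry hit the expected score extremes", {
  n <- 978
  ids <- sprintf("G%04d", seq_len(n))
  up <- ids[(n - 52):n]    # 53 up genes at the bottom
  down <- ids[1:42]        # 42 down genes at the top
  rev <- compute_rges(ids, toy_signature(up, down))
  expect_lte(rev$rges, -1.5)

  mim <- compute_rges(ids, toy_signature(up = ids[1:53],
                                         down = ids[(n - 41):n]))
  expect_gte(mim$rges, 1.5)
})

test_that("scores stay bounded over fuzzed rankings and random sets", {
  set.seed(21)
  ids <- sprintf("g%03d", 1:200)
  for (i in 1:500) {
    perm <- sample(ids)
    up <- sample(ids, sample(2:20, 1))
    down <- sample(setdiff(ids, up), sample(2:20, 1))
    out <- compute_rges(perm, toy_signature(up, down))
    expect_true(abs(out$es_up) <= 1 && abs(out$es_down) <= 1)
    expect_true(out$rges >= -2 && out$rges <= 2)
  }
})

test_that("sRGES summarization honors the reference-condition adjustment", {
  rec <- function(compound, rges, dose = 10, dur = 24) {
    tibble::tibble(profile_id = paste0(compound, dose, dur, rges),
                   compound = compound, cell_line = "PC3", dose_um = dose,
                   duration_h = dur, is_gold = TRUE, rges = rges)
  }
  # single reference profile: identity
  s1 <- summarize_rges(rec("a", -1.2))
  expect_equal(s1$srges, -1.2)
  # two reference profiles: plain mean
  s2 <- summarize_rges(dplyr::bind_rows(rec("a", -1.0), rec("a", -0.5)))
  expect_equal(s2$srges, -0.75)
  # low-dose record adjusted by the supplied global offset
  recs <- dplyr::bind_rows(rec("a", -1.0), rec("a", -0.4, dose = 5))
  s3 <- summarize_rges(recs, dose_offset = 0.6)
  expect_equal(s3$srges, -1.0)
  # record order never matters
  set.seed(5)
  many <- dplyr::bind_rows(
    rec("a", -1), rec("a", -0.2, dose = 5), rec("b", 0.3),
    rec("b", 0.8, dur = 6), rec("c", -0.5)
  )
  s4 <- summarize_rges(many)
  s5 <- summarize_rges(many[sample(nrow(many)), ])
  expect_equal(s4, s5)
})

test_that("estimated condition offsets recenter off-reference profiles", {
  # compounds seen at both doses carry a +0.5 offset at low dose
  rec <- tibble::tibble(
    profile_id = as.character(1:6),
    compound = c("a", "a", "b", "b", "c", "c"),
    cell_line = "PC3",
    dose_um = c(5, 10, 5, 10, 10, 10),
    duration_h = 24, is_gold = TRUE,
    rges = c(-0.5, -1.0, 0.0, -0.5, -1.0, -1.0)
  )
  out <- summarize_rges(rec)
  # estimated dose offset is mean of (-0.5 - -1.0, 0.0 - -0.5) = 0.5
  expect_equal(out$srges[out$compound == "a"], -1.0)
  expect_equal(out$srges[out$compound == "b"], -0.5)
  expect_equal(out$srges[out$compound == "c"], -1.0)
})

test_that("direct similarity metrics behave on canonical vectors", {
  x <- c(a = 1, b = 2, c = 3)
  expect_equal(unlist(similarity_metrics(x, x)[1, 1:3]),
               c(spearman = 1, pearson = 1, cosine = 1))
  expect_equal(unlist(similarity_metrics(x, -x)[1, 1:3]),
               c(spearman = -1, pearson = -1, cosine = -1))
  y <- c(a = 1, b = 3, c = 2)
  expect_equal(similarity_metrics(x, y)$spearman, 0.5)
  expect_warning(out <- similarity_metrics(x, c(a = 1, b = 1, c = 1)),
                 "constant")
  expect_true(is.na(out$spearman) && !is.na(out$cosine))
  expect_error(similarity_metrics(x[1:2], x[1:2]), ">= 3")
})

test_that("condition contrasts use the rank-sum test correctly", {
  rec <- tibble::tibble(
    profile_id = as.character(1:20), compound = rep(letters[1:10], 2),
    cell_line = "PC3",
    dose_um = rep(c(5, 10), each = 10), duration_h = 24, is_gold = TRUE,
    rges = c(1:10, 1:10)
  )
  out <- condition_contrast(rec, "dose")
  expect_gt(out$p_value, 0.99)  # identical groups

  rec2 <- rec
  rec2$rges <- c(1:10, 11:20)
  out2 <- condition_contrast(rec2, "dose")
  expect_lt(out2$p_value, 0.001)

  expect_error(condition_contrast(rec[10:20, ], "dose"), ">= 2")
})

test_that("reversal is stronger at the reference condition in the cohort", {
  hits <- vapply(1:10, function(seed) {
    cfg <- small_config(seed = 100 + seed, n_compounds = 40L)
    truth <- simulate_ground_truth(cfg)
    prof <- simulate_compound_profiles(cfg, truth)
    sig <- toy_signature(truth$planted_up_genes, truth$planted_down_genes)
    r <- score_profiles(prof, sig)
    cc <- condition_contrast(r, "dose")
    cc$mean_high < cc$mean_low
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
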