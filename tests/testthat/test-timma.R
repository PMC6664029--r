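test_that("sensitivity rescaling is a monotone map onto [0, 1]", {
  expect_equal(rges_to_sensitivity(c(a = -2, b = 0, c = 2)),
               c(a = 1, b = 0.5, c = 0))
  expect_equal(rges_to_sensitivity(c(a = -1, b = 1)), c(a = 1, b = 0))
  set.seed(4)
  s <- setNames(rnorm(20), paste0("d", 1:20))
  y <- rges_to_sensitivity(s)
  expect_true(all(diff(y[order(s)]) <= 0))
  expect_error(rges_to_sensitivity(c(a = 1, b = 1)), "constant")
  expect_error(rges_to_sensitivity(1:3), "named")
})

test_that("target-set predictions follow the subset/superset bounds", {
  m <- rbind(A = c(1, 0), B = c(1, 1))
  colnames(m) <- c("t1", "t2")
  y <- c(A = 0.3, B = 0.8)
  expect_equal(timma_predict(c("t1", "t2"), m, y), 0.8) # exact match B
  expect_equal(timma_predict("t2", m, y), 0.4)          # L=0, U=0.8
  expect_equal(timma_predict("t1", m, y), 0.3)          # exact match A

  # no related drugs: uninformative default (0 + 1) / 2
  m2 <- rbind(A = c(1, 0, 0))
  colnames(m2) <- c("t1", "t2", "t3")
  expect_equal(timma_predict(c("t2", "t3"), m2, c(A = 0.6)), 0.5)

  expect_error(timma_predict("zz", m, y), "unknown target")
  expect_error(timma_predict("t1", m, c(A = 0.3, B = 1.2)), "\\[0, 1\\]")
})

test_that("predictions are monotone and self-consistent under a monotone truth", {
  for (seed in 1:20) {
    inst <- random_monotone_instance(n_targets = sample(4:8, 1),
                                     n_drugs = sample(5:15, 1), seed = seed)
    subsets <- all_subsets(inst$targets)
    yhat <- vapply(subsets, function(s) timma_predict(s, inst$matrix, inst$y),
                   numeric(1))
    truthv <- vapply(subsets, inst$f, numeric(1))

    # monotone along every edge T -> T + {t} (implies all subset pairs);
    # subsets are in bit-code order, so the superset index is direct
    nt <- length(inst$targets)
    mono_ok <- TRUE
    for (code in 0:(2^nt - 1)) {
      for (b in seq_len(nt) - 1) {
        if (bitwAnd(code, 2^b) == 0) {
          mono_ok <- mono_ok &&
            yhat[code + 1] <= yhat[code + 2^b + 1] + 1e-12
        }
      }
    }
    expect_true(mono_ok)

    # interval bracketing of the noiseless truth
    brackets <- vapply(seq_along(subsets), function(i) {
      in_T <- inst$targets %in% subsets[[i]]
      sub <- inst$matrix %*% (1 - in_T) == 0
      sup <- (1 - inst$matrix) %*% in_T == 0
      L <- if (any(sub)) max(inst$y[sub]) else 0
      U <- if (any(sup)) min(inst$y[sup]) else 1
      abs(yhat[i] - truthv[i]) <= (U - L) / 2 + 1e-12
    }, logical(1))
    expect_true(all(brackets))

    # every drug's own target set predicts the mean of its observed y
    selfc <- vapply(rownames(inst$matrix), function(d) {
      own <- inst$targets[inst$matrix[d, ] == 1]
      same <- apply(inst$matrix, 1, function(r) {
        setequal(inst$targets[r == 1], own)
      })
      isTRUE(all.equal(timma_predict(own, inst$matrix, inst$y),
                       mean(inst$y[same])))
    }, logical(1))
    expect_true(all(selfc))
  }
})

test_that("synergy scores evaluate the three reference models literally", {
  expect_equal(synergy_scores(0.5, 0.4, 0.9)$s_a, 0)
  expect_equal(synergy_scores(0.5, 0.4, 0.2)$s_m, 0)
  expect_equal(synergy_scores(0.5, 0.4, 0.5)$s_l, 0)
  out <- synergy_scores(0.3, 0.6, 0.7)
  expect_equal(out$s_a, 0.7 - 0.9)
  expect_equal(out$s_m, 0.7 - 0.18)
  expect_equal(out$s_l, 0.7 - 0.6)
  expect_error(synergy_scores(0.5, 0.4, 1.2), "\\[0, 1\\]")
})

test_that("average synergy enumerates target pairs and skips shared targets", {
  m <- rbind(A = c(1, 1, 0), B = c(0, 0, 1))
  colnames(m) <- c("t1", "t2", "t3")
  y <- c(A = 0.6, B = 0.3)
  # two targets x one target: mean over the 2 pairs, via explicit enumeration
  s_hand <- mean(c(
    timma_predict(c("t1", "t3"), m, y) -
      (timma_predict("t1", m, y) + timma_predict("t3", m, y)),
    timma_predict(c("t2", "t3"), m, y) -
      (timma_predict("t2", m, y) + timma_predict("t3", m, y))
  ))
  expect_equal(average_synergy("A", "B", m, y, "additive"), s_hand)

  # single-target drugs: one pair only
  m2 <- rbind(C = c(1, 0), D = c(0, 1))
  colnames(m2) <- c("t1", "t2")
  y2 <- c(C = 0.2, D = 0.5)
  one <- timma_predict(c("t1", "t2"), m2, y2) -
    (timma_predict("t1", m2, y2) + timma_predict("t2", m2, y2))
  expect_equal(average_synergy("C", "D", m2, y2, "additive"), one)

  # identical single-target drugs leave no valid pair
  m3 <- rbind(E = 1, F = 1)
  colnames(m3) <- "t1"
  expect_error(average_synergy("E", "F", m3, c(E = 0.1, F = 0.2)),
               "no valid target pairs")
  expect_error(average_synergy("A", "zz", m, y), "not in matrix")
})

test_that("combination sensitivity adds expectation and synergy with clipping", {
  inst <- random_monotone_instance(6, 10, seed = 33)
  d <- rownames(inst$matrix)[1:2]
  out <- combination_sensitivity(d[1], d[2], inst$matrix, inst$y)
  union_set <- inst$targets[inst$matrix[d[1], ] == 1 | inst$matrix[d[2], ] == 1]
  expect_equal(out$expectation, timma_predict(union_set, inst$matrix, inst$y))
  expect_equal(out$predicted_sensitivity,
               min(1, max(0, out$expectation + out$average_synergy)))
  expect_true(out$predicted_sensitivity >= 0 && out$predicted_sensitivity <= 1)

  # symmetric in the drug pair for additive and multiplicative kinds
  swap <- combination_sensitivity(d[2], d[1], inst$matrix, inst$y)
  expect_equal(out$s_a, swap$s_a)
  expect_equal(out$s_m, swap$s_m)
  expect_equal(out$expectation, swap$expectation)

  # independence expectation uses the Bliss-style null
  alt <- combination_sensitivity(d[1], d[2], inst$matrix, inst$y,
                                 expectation_kind = "independence")
  expect_equal(alt$expectation,
               1 - (1 - inst$y[[d[1]]]) * (1 - inst$y[[d[2]]]))
})

test_that("the pair screen ranks by predicted sensitivity", {
  inst <- random_monotone_instance(6, 8, seed = 44)
  scr <- synergy_screen(inst$matrix, inst$y)
  expect_true(all(diff(scr$pairs$predicted_sensitivity) <= 0))
  expect_lte(nrow(scr$pairs), choose(8, 2))
  gl <- glance(scr)
  expect_equal(gl$n_pairs, nrow(scr$pairs))
  expect_equal(gl$top_sensitivity, scr$pairs$predicted_sensitivity[1])
  expect_s3_class(autoplot(scr), "ggplot")
})
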