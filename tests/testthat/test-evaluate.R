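test_that("ROC curves sweep thresholds with tie grouping and polarity", {
  roc <- roc_curve(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(roc[1, ], c(fpr = 0, tpr = 0))
  expect_equal(roc[nrow(roc), ], c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc[, 1]) >= 0) && all(diff(roc[, 2]) >= 0))

  # perfect separation passes through (0, 1)
  perfect <- roc_curve(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_true(any(perfect[, 1] == 0 & perfect[, 2] == 1))
  # complete ties collapse to the diagonal segment
  tied <- roc_curve(rep(1, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied, cbind(fpr = c(0, 1), tpr = c(0, 1)),
               ignore_attr = TRUE)
  # negating scores under flipped polarity leaves the curve unchanged
  s <- c(0.3, -0.1, 0.7, 0.2, -0.5); l <- c(1, 0, 1, 0, 0)
  expect_equal(roc_curve(s, l, "high_scores_positive"),
               roc_curve(-s, l, "low_scores_positive"))
  expect_error(roc_curve(1:3, c(1, 1, 1)), "at least one")
})

test_that("AUC equals the pairwise-comparison oracle, with and without ties", {
  expect_equal(auc(roc_curve(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0))), 0.75)
  expect_equal(auc(roc_curve(rep(1, 4), c(1, 0, 1, 0))), 0.5)
  set.seed(71)
  for (i in 1:60) {
    k <- sample(4:8, 1)
    scores <- sample(seq(0, 1, 0.25), k, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, k - 2, replace = TRUE))
    got <- auc(roc_curve(scores, labels))
    expect_equal(got, auc_oracle(scores, labels), tolerance = 1e-12)
    # complement identity for the same data
    expect_equal(auc(roc_curve(-scores, labels)) + got, 1,
                 tolerance = 1e-12)
  }
})

test_that("AUC and read-off metrics agree with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(72)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.3)
  scores[labels == 1] <- scores[labels == 1] + 1
  roc <- roc_curve(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(auc(roc), as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("partial AUC is standardized, interpolated and consistent", {
  perfect <- roc_curve(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(partial_auc(perfect, 0.5), 1)
  roc <- roc_curve(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0))
  expect_equal(partial_auc(roc, 1, standardized = TRUE), auc(roc))
  # nondecreasing in the FPR cap when unstandardized
  caps <- seq(0.1, 1, 0.1)
  areas <- vapply(caps, function(f) partial_auc(roc, f, FALSE), 1)
  expect_true(all(diff(areas) >= -1e-14))
  # interpolation midway along the flat segment before the second positive
  expect_equal(partial_auc(roc, 0.25, standardized = FALSE), 0.25 * 0.5)
})

test_that("threshold read-offs walk the curve as specified", {
  roc <- roc_curve(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0))
  expect_equal(sensitivity_at_fpr(roc, 0.5), 1.0)
  expect_equal(sensitivity_at_fpr(roc, 0), 0.5)
  expect_equal(specificity_at_tpr(roc, 0.7), 0.5)
  expect_equal(specificity_at_tpr(roc, 0), 1.0)
  perfect <- roc_curve(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(sensitivity_at_fpr(perfect, 0.1), 1.0)
  expect_equal(specificity_at_tpr(perfect, 0.7), 1.0)
})

test_that("metrics are invariant under strictly monotone score transforms", {
  set.seed(73)
  scores <- rnorm(80); labels <- rbinom(80, 1, 0.4)
  labels[1:2] <- 0:1
  r1 <- roc_curve(scores, labels)
  r2 <- roc_curve(exp(2 * scores) + 5, labels)
  expect_equal(r1, r2)
})

test_that("category evaluation uses the documented polarity per class", {
  set.seed(74)
  ids <- sprintf("G%02d", 1:20)
  v <- matrix(rnorm(400), 20, 20)
  S <- shared_fm(v, ids)
  ps_pairs <- rbind(c("G01", "G02"), c("G03", "G04"))
  v[1, 2] <- v[2, 1] <- v[3, 4] <- v[4, 3] <- 10   # top positive scores
  S <- shared_fm(v, ids)
  cat_ <- interaction_catalog(PS = ps_pairs, SL = rbind(c("G05", "G06")))
  ev <- evaluate_category(S, cat_, "PS")
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$n_pos, 4L)
  # SL ranks the most negative first: the same top entries score poorly
  v2 <- v; v2[5, 6] <- v2[6, 5] <- -10
  ev2 <- evaluate_category(shared_fm(v2, ids), cat_, "SL")
  expect_equal(ev2$auc, 1.0)
  # flipping polarity maps AUC to 1 - AUC (tie-free scores)
  ev3 <- evaluate_category(S, cat_, "PS", polarity = "low_scores_positive")
  expect_equal(ev3$auc, 1 - ev$auc, tolerance = 1e-12)
})

test_that("parameter adjustment maximizes the objective with the tie rule", {
  set.seed(75)
  sim <- generate_screen(screen_design(n_arrays = 60, n_queries = 30,
                                       seed = 9))
  cat_ <- truth_catalog(sim$truth)
  grid <- data.frame(p = c(0.3, 0.55), q = c(0.3, 0.95))
  res <- adjust_parameters(sim$W, cat_, "adjusted_positive", grid,
                           scoring_positive = "product")
  expect_true(res$p %in% grid$p)
  expect_equal(res$objective, max(res$trace$objective, na.rm = TRUE))

  # on a constant matrix every grid point gives identical (tied) scores:
  # the smallest (p, q) wins
  ids <- sprintf("G%02d", 1:15)
  null_ <- shared_fm(matrix(1, 15, 15), ids)
  cat2 <- interaction_catalog(PS = rbind(c("G01", "G02")),
                              SL = rbind(c("G03", "G04")),
                              SS = rbind(c("G05", "G06")),
                              PE = rbind(c("G07", "G08")))
  grid2 <- data.frame(p = c(0.7, 0.2, 0.2), q = c(0.2, 0.7, 0.2))
  res2 <- adjust_parameters(null_, cat2, "fixed", grid2)
  expect_equal(c(res2$p, res2$q), c(0.2, 0.2))
})
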