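test_that("sign fixing flips all-negative factors without changing the fit", {
  d <- decomposition(x = c(A = -1, B = -2, C = -3), y = c(X = -1, Y = -2),
                     method = "arf", params = list())
  fit_before <- d$x %o% d$y
  d2 <- fix_sign(d)
  expect_equal(unname(d2$x), c(1, 2, 3))
  expect_equal(unname(d2$y), c(1, 2))
  expect_equal(d2$x %o% d2$y, fit_before)

  d3 <- decomposition(x = c(A = 1, B = 2), y = c(X = 5), "qma", list())
  expect_identical(fix_sign(d3)$x, d3$x)
})

test_that("median-ratio scaling satisfies the outer-product contract", {
  ids <- c("A", "B", "C")
  d <- decomposition(x = setNames(c(1, 2, 2), ids),
                     y = setNames(c(2, 4, 4), ids), "qma", list())
  W <- shared_fm(d$x %o% d$y, ids)
  smf <- scale_single_mutant_fitness(d, W)
  expect_equal(smf$M, 1)
  expect_equal(unname(smf$w), sqrt(2) * c(1, 2, 2))
  # w[a] * w[b] reproduces the rank-one fit on every shared pair
  expect_equal(smf$w %o% smf$w, d$x %o% d$y, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("negative shared ratios are excluded from the median", {
  ids <- c("A", "B", "C")
  x <- setNames(c(1, 1, 1), ids)
  y <- setNames(c(-1, 2, 4), ids)
  d <- decomposition(x, y, "qma", list())
  smf <- scale_single_mutant_fitness(d, shared_fm(matrix(1, 3, 3), ids))
  # ratios after unit normalization: (-1, 2, 4) * |x|/|y|; median of the
  # retained nonnegative pair
  expect_equal(smf$M, median(c(2, 4)) * sqrt(3 / 21))

  d2 <- decomposition(setNames(1:2, c("A", "B")),
                      setNames(1:2, c("X", "Y")), "qma", list())
  expect_error(
    scale_single_mutant_fitness(d2, fm(matrix(1, 2, 2),
                                       arr = c("A", "B"),
                                       qry = c("X", "Y"))),
    "no mutant is shared")
  d3 <- decomposition(setNames(c(1, 1), c("A", "B")),
                      setNames(c(-1, -2), c("A", "B")), "qma", list())
  expect_error(
    scale_single_mutant_fitness(d3, shared_fm(matrix(1, 2, 2),
                                              c("A", "B"))),
    "all shared-mutant ratios are negative")
})

test_that("screen-effect correction maps the exact null onto w outer w", {
  set.seed(51)
  ids <- sprintf("G%02d", 1:12)
  w_true <- runif(12, 0.3, 1.1)
  g <- runif(12, 0.5, 2)  # per-screen technical factors
  W <- shared_fm(outer(w_true, w_true * g), ids)
  dec <- fix_sign(qma(W, 0.5, 0.5))
  smf <- scale_single_mutant_fitness(dec, W)
  Wc <- correct_screen_effects(W, dec, smf)
  expect_equal(unclass(Wc), smf$w %o% smf$w, tolerance = 1e-10,
               ignore_attr = TRUE)

  # doubling one screen's factor leaves the corrected matrix unchanged
  # (the largest factor, so the median ratio keeps its value)
  W2v <- unclass(W); j <- which.max(g); W2v[, j] <- 2 * W2v[, j]
  W2 <- shared_fm(W2v, ids)
  dec2 <- fix_sign(qma(W2, 0.5, 0.5))
  smf2 <- scale_single_mutant_fitness(dec2, W2)
  Wc2 <- correct_screen_effects(W2, dec2, smf2)
  expect_equal(unclass(Wc2), unclass(Wc), tolerance = 1e-10)
})

test_that("correction propagates missingness and undefined queries", {
  set.seed(52)
  ids <- sprintf("G%02d", 1:8)
  v <- outer(runif(8, 0.5, 1.5), runif(8, 0.5, 1.5))
  v[2, 3] <- NA
  W <- shared_fm(v, ids)
  dec <- fix_sign(qma(W, 0.5, 0.5))
  smf <- scale_single_mutant_fitness(dec, W)
  Wc <- correct_screen_effects(W, dec, smf)
  expect_true(is.na(unclass(Wc)[2, 3]))
  expect_equal(sum(is.na(Wc)), 1L)

  # a query whose factor is undefined yields a fully missing column
  dec$y[4] <- NA; dec$y_defined[4] <- FALSE
  Wc2 <- correct_screen_effects(W, dec, smf)
  expect_true(all(is.na(unclass(Wc2)[, 4])))
})
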