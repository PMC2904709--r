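test_that("screens are reproducible and honor the design", {
  des <- screen_design(n_arrays = 40, n_queries = 20, seed = 5)
  s1 <- generate_screen(des)
  s2 <- generate_screen(des)
  expect_identical(unclass(s1$W), unclass(s2$W))
  expect_identical(s1$truth$w_true, s2$truth$w_true)
  expect_equal(dim(s1$W), c(40L, 20L))
  # all queries drawn from the array collection at shared_fraction 1
  expect_true(all(query_ids(s1$W) %in% array_ids(s1$W)))
  # a partly disjoint query set
  s3 <- generate_screen(screen_design(n_arrays = 40, n_queries = 20,
                                      shared_fraction = 0.5, seed = 5))
  expect_equal(sum(query_ids(s3$W) %in% array_ids(s3$W)), 10L)
})

test_that("the noise-free unplanted screen is exactly rank-one and recoverable", {
  des <- screen_design(n_arrays = 60, n_queries = 25, noise_sigma = 0,
                       missing_rate = 0, screen_factor_range = c(1, 1),
                       interaction_rates = c(SL = 0, SS = 0, PE = 0,
                                             PS = 0),
                       seed = 8)
  sim <- generate_screen(des)
  d <- qma(sim$W, 0.55, 0.95)
  expect_lt(max(abs(d$x %o% d$y - unclass(sim$W))), 1e-10)
  smf <- scale_single_mutant_fitness(fix_sign(d), sim$W)
  expect_equal(unname(smf$w),
               unname(sim$truth$w_true[names(smf$w)]),
               tolerance = 1e-8)
})

test_that("planted interactions follow their construction rules", {
  des <- screen_design(n_arrays = 80, n_queries = 40, noise_sigma = 0,
                       missing_rate = 0,
                       interaction_rates = c(SL = 0.01, SS = 0.01,
                                             PE = 0.01, PS = 0.01),
                       seed = 13)
  sim <- generate_screen(des)
  v <- unclass(sim$W)
  pl <- sim$truth$planted
  # planted sets are pairwise disjoint
  cells <- lapply(pl, function(p) paste(p[, 1], p[, 2]))
  expect_equal(anyDuplicated(unlist(cells)), 0L)
  # SL entries are exactly zero before missingness
  sl <- pl$SL
  expect_true(all(v[cbind(match(sl[, 1], array_ids(sim$W)),
                          match(sl[, 2], query_ids(sim$W)))] == 0))
  # PS entries exceed the fitness of the less-fit single mutant
  ps <- pl$PS
  wt <- sim$truth$w_true
  g <- sim$truth$screen_factors
  idx <- cbind(match(ps[, 1], array_ids(sim$W)),
               match(ps[, 2], query_ids(sim$W)))
  expect_true(all(v[idx] > pmin(wt[ps[, 1]], wt[ps[, 2]]) *
                    g[ps[, 2]] * 1.1 - 1e-12))
  # the truth catalog exports every planted pair
  cat_ <- truth_catalog(sim$truth)
  expect_equal(length(cat_$SL), nrow(unique(
    cbind(pmin(sl[, 1], sl[, 2]), pmax(sl[, 1], sl[, 2])))))
})

test_that("missingness lands near the design rate for both mechanisms", {
  des <- screen_design(n_arrays = 120, n_queries = 60,
                       missing_rate = 0.20, seed = 17)
  sim <- generate_screen(des)
  expect_lt(abs(mean(is.na(sim$W)) - 0.20), 0.01)

  desf <- screen_design(n_arrays = 120, n_queries = 60,
                        missing_rate = 0.20,
                        missing_mechanism = "fitness_dependent",
                        seed = 17)
  simf <- generate_screen(desf)
  expect_lt(abs(mean(is.na(simf$W)) - 0.20), 0.03)
  # low-fitness entries are filtered more often than high-fitness ones
  ref <- generate_screen(screen_design(n_arrays = 120, n_queries = 60,
                                       missing_rate = 0,
                                       missing_mechanism = "fitness_dependent",
                                       seed = 17))$W
  lost <- is.na(unclass(simf$W))
  expect_gt(mean(unclass(ref)[!lost]), mean(unclass(ref)[lost]))
})

test_that("invalid designs are rejected", {
  expect_error(screen_design(missing_rate = 1.2))
  expect_error(screen_design(interaction_rates = c(SL = 0.3, SS = 0.3)))
  expect_error(screen_design(interaction_rates = c(XX = 0.01)))
  expect_error(screen_design(screen_factor_range = c(-1, 2)))
})
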