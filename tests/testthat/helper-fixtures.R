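# Shared fixtures and independent oracles for the test suite.

fm <- function(values, arr = NULL, qry = NULL) {
  values <- as.matrix(values)
  if (is.null(arr)) arr <- sprintf("A%03d", seq_len(nrow(values)))
  if (is.null(qry)) qry <- sprintf("Q%03d", seq_len(ncol(values)))
  fitness_matrix(values, arr, qry)
}

# complete strictly positive rank-one matrix with known factors
rank_one_fm <- function(n, m, seed, lo = 0.2, hi = 2) {
  set.seed(seed)
  u <- runif(n, lo, hi); v <- runif(m, lo, hi)
  list(W = fm(u %o% v), u = u, v = v)
}

# symmetric square screen: array ids reused as query ids
shared_fm <- function(values, ids) fitness_matrix(values, ids, ids)

# Mann-Whitney pairwise-comparison AUC oracle (ties count one half)
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive h-subset least-trimmed-squares oracle
lts_oracle <- function(x, y, t, intercept) {
  k <- length(x); h <- ceiling(t * k)
  ols <- function(xs, ys) {
    if (intercept) unname(coef(lm(ys ~ xs))[c(2, 1)]) else
      c(sum(xs * ys) / sum(xs^2), 0)
  }
  best <- NULL; best_obj <- Inf
  for (sub in combn(k, h, simplify = FALSE)) {
    f <- ols(x[sub], y[sub])
    if (any(!is.finite(f))) next
    obj <- sum(sort((y - f[1] * x - f[2])^2)[seq_len(h)])
    if (obj < best_obj) { best_obj <- obj; best <- f }
  }
  list(slope = best[1], intercept = best[2], objective = best_obj)
}

# write a simplified 3-column interaction table
write_pairs_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}
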