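# Zero tolerance below which a factor component cannot be divided by;
# affected downstream entries become missing rather than non-finite.
.EPISCREEN_ZERO_TOL <- 1e-12

#' Order-statistic quantile with linear interpolation
#'
#' The quantile convention used throughout the decomposition: linear
#' interpolation between order statistics at plotting position
#' (i - 1)/(k - 1) for k sorted values (R's type-7 quantile).
#'
#' @param values Non-empty numeric vector.
#' @param level Quantile level in \[0, 1\].
#' @return The interpolated quantile as a single number.
#' @export
qma_quantile <- function(values, level) {
  if (length(values) == 0L) stop("cannot take a quantile of an empty set")
  stopifnot(level >= 0, level <= 1)
  stats::quantile(values, probs = level, type = 7, names = FALSE)
}

#' Rank-one decomposition container
#'
#' Holds the array factor `x` (length n) and query factor `y` (length m) of
#' a rank-one approximation of a fitness matrix, together with definedness
#' masks for components that could not be estimated (too few observed
#' entries, or a near-zero divisor) and the method/parameter provenance.
#' The fitted value for entry (a, b) is `x[a] * y[b]`, defined only where
#' both components are defined. Undefined components are `NA`.
#'
#' @param x,y Numeric factor vectors named by array/query identifiers.
#' @param method `"qma"` or `"arf"`.
#' @param params List of the parameters the decomposition was run with.
#' @return An object of class `decomposition`.
#' @export
decomposition <- function(x, y, method, params) {
  structure(list(x = x, y = y,
                 x_defined = !is.na(x), y_defined = !is.na(y),
                 method = method, params = params),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("rank-one decomposition (%s): %d array, %d query components (%d/%d defined)\n",
              x$method, length(x$x), length(x$y),
              sum(x$x_defined), sum(x$y_defined)))
  invisible(x)
}

#' Quantile-based matrix approximation (QMA)
#'
#' One-pass rank-one decomposition of a double-mutant fitness matrix under
#' the multiplicative model. The array factor `x` collects the p-quantiles
#' of the rows of W; rows in which a strict majority of the observed
#' entries are negative (as occurs in zero-centered E-MAP-style data) use
#' the (1-p)-quantile instead, so that the factor keeps the sign of the
#' bulk of the row. The rows of W are then divided component-wise by `x`,
#' and the query factor `y` collects the q-quantiles of the columns of the
#' row-scaled matrix. No iteration is performed: on a complete positive
#' rank-one matrix a single pass is already exact for any (p, q). With
#' p = q = 0.5 the procedure reduces to a one-pass multiplicative
#' median sweep.
#'
#' Components estimated from fewer than 2 observed entries, or with a
#' magnitude below the zero tolerance (1e-12), are marked undefined.
#'
#' @param W A [fitness_matrix()].
#' @param p Quantile level for the rows, in (0, 1).
#' @param q Quantile level for the columns, in (0, 1).
#' @return A [decomposition()] with `method = "qma"`.
#' @examples
#' W <- fitness_matrix(matrix(c(1, 2, 2, 4), 2, 2),
#'                     array_ids = c("A", "B"), query_ids = c("C", "D"))
#' d <- qma(W, p = 0.5, q = 0.5)
#' d$x %o% d$y   # reconstructs W exactly
#' @export
qma <- function(W, p = 0.5, q = 0.5) {
  stopifnot(inherits(W, "fitness_matrix"))
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  v <- unclass(W)
  if (all(is.na(v))) stop("cannot decompose a fully missing matrix")
  n <- nrow(v); m <- ncol(v)

  x <- rep(NA_real_, n)
  for (a in seq_len(n)) {
    obs <- v[a, !is.na(v[a, ])]
    if (length(obs) < 2L) next
    level <- if (sum(obs < 0) > length(obs) / 2) 1 - p else p
    xa <- qma_quantile(obs, level)
    if (abs(xa) >= .EPISCREEN_ZERO_TOL) x[a] <- xa
  }

  wt <- v / x  # row-scaled matrix; rows with undefined x become all-NA
  y <- rep(NA_real_, m)
  for (b in seq_len(m)) {
    obs <- wt[!is.na(wt[, b]), b]
    if (length(obs) < 2L) next
    y[b] <- qma_quantile(obs, q)
  }

  names(x) <- array_ids(W); names(y) <- query_ids(W)
  decomposition(x, y, method = "qma", params = list(p = p, q = q))
}
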