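#' SVD-based initial query factor
#'
#' Initial estimate of the query factor for alternating robust fitting:
#' the unit-length leading right singular vector of the fitness matrix
#' with missing entries substituted by ones, sign-fixed so that the vector
#' has a nonnegative sum.
#'
#' @param W A [fitness_matrix()].
#' @return Unit numeric vector of length `ncol(W)`.
#' @export
svd_init <- function(W) {
  stopifnot(inherits(W, "fitness_matrix"))
  A <- unclass(W)
  A[is.na(A)] <- 1
  if (all(A == 0)) stop("cannot initialize from an all-zero matrix")
  v <- svd(A, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(v) < 0) v <- -v
  stats::setNames(v, query_ids(W))
}

# Ordinary least squares for one predictor, optionally with an intercept.
# Returns c(slope, intercept); intercept is 0 when not fitted. NULL when
# the system is singular (all predictors zero / constant).
.ols1 <- function(x, y, intercept) {
  if (intercept) {
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    if (sxx < .Machine$double.eps * length(x)) return(NULL)
    b <- sum((x - mx) * (y - my)) / sxx
    c(b, my - b * mx)
  } else {
    sxx <- sum(x^2)
    if (sxx < .Machine$double.eps * length(x)) return(NULL)
    c(sum(x * y) / sxx, 0)
  }
}

#' Least trimmed squares fit of a single-predictor regression
#'
#' Fits `response ~ slope * predictor` (plus an optional intercept) by
#' least trimmed squares: the coefficients minimize the sum of the
#' h = ceiling(t * k) smallest squared residuals over the k points, which
#' makes the fit resistant to up to (1 - t) gross outliers. The optimum is
#' searched with elemental starts followed by concentration steps (refit on
#' the h best-fitting points until the objective stops decreasing). When
#' the number of distinct elemental subsets is small (at most 100) all of
#' them are used deterministically; otherwise `n_starts` random subsets
#' are drawn under `seed`.
#'
#' @param predictors,responses Numeric vectors of equal length (>= 2).
#' @param t Trimming fraction in (0.5, 1]; `t = 1` is ordinary least
#'   squares.
#' @param intercept Logical; fit a nuisance intercept term.
#' @param n_starts Number of random elemental starts when exhaustive
#'   enumeration of elemental subsets is too large.
#' @param seed Integer seed for the random starts, or `NULL` to draw from
#'   the current RNG stream. The caller's RNG state is never disturbed
#'   when a seed is given.
#' @return List with `slope`, `intercept` (`NA` when not fitted), and
#'   `objective` (the trimmed sum of squares); or `NULL` when fewer than
#'   2 points are available (the caller marks the component undefined).
#' @export
lts_fit <- function(predictors, responses, t = 0.75, intercept = FALSE,
                    n_starts = 20L, seed = NULL) {
  stopifnot(length(predictors) == length(responses))
  stopifnot(t > 0.5, t <= 1)
  k <- length(predictors)
  if (k < 2L) return(NULL)
  h <- as.integer(ceiling(t * k))
  if (h < 2L) return(NULL)
  npar <- if (intercept) 2L else 1L

  trimmed_obj <- function(fit) {
    r2 <- (responses - fit[1L] * predictors - fit[2L])^2
    sum(sort(r2, partial = h)[seq_len(h)])
  }

  if (h >= k) {  # no trimming: plain OLS
    fit <- .ols1(predictors, responses, intercept)
    if (is.null(fit)) fit <- c(0, if (intercept) mean(responses) else 0)
    return(list(slope = fit[1L],
                intercept = if (intercept) fit[2L] else NA_real_,
                objective = trimmed_obj(fit)))
  }

  # candidate elemental subsets
  if (npar == 1L) {
    subsets <- as.list(seq_len(k))
  } else {
    subsets <- utils::combn(k, 2L, simplify = FALSE)
  }
  if (length(subsets) > 100L) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    subsets <- lapply(seq_len(n_starts),
                      function(i) sample.int(k, npar))
  }

  best <- NULL; best_obj <- Inf
  for (sub in subsets) {
    fit <- .ols1(predictors[sub], responses[sub], intercept)
    if (is.null(fit)) next
    obj <- trimmed_obj(fit)
    # concentration steps: refit on the h points with smallest residuals
    for (iter in seq_len(50L)) {
      r2 <- (responses - fit[1L] * predictors - fit[2L])^2
      keep <- order(r2)[seq_len(h)]
      newfit <- .ols1(predictors[keep], responses[keep], intercept)
      if (is.null(newfit)) break
      newobj <- trimmed_obj(newfit)
      if (newobj >= obj - 1e-14 * (1 + obj)) {
        if (newobj < obj) { fit <- newfit; obj <- newobj }
        break
      }
      fit <- newfit; obj <- newobj
    }
    if (obj < best_obj) { best <- fit; best_obj <- obj }
  }
  if (is.null(best)) return(NULL)
  list(slope = best[1L],
       intercept = if (intercept) best[2L] else NA_real_,
       objective = best_obj)
}

#' Alternating robust fitting (ARF)
#'
#' Rank-one decomposition of a fitness matrix by alternating regression of
#' its rows and columns, using least trimmed squares in place of ordinary
#' least squares so that extreme fitness measurements (synthetic-lethal or
#' strongly suppressing pairs) do not distort the factors. Starting from an
#' SVD-based unit query factor `y` (see [svd_init()]), each row of W is
#' regressed on `y` over its observed entries to update the array factor
#' `x`; each column is then regressed on `x` to update `y`. After every
#' full sweep `y` is renormalized to unit length, with the scale absorbed
#' into `x`. Iteration stops when the maximum relative change of the
#' factors falls below `tol` or after `max_iter` sweeps. An intercept, if
#' requested, is fitted as a nuisance term in each regression but excluded
#' from the factors; the fitted value remains `x[a] * y[b]`.
#'
#' Rows or columns with fewer than 2 usable points yield undefined
#' components.
#'
#' @param W A [fitness_matrix()].
#' @param t Trimming fraction in (0.5, 1] for the row/column regressions.
#' @param intercept Logical; include a nuisance intercept in each
#'   regression.
#' @param max_iter Maximum number of alternating sweeps.
#' @param tol Relative-change convergence tolerance.
#' @param n_starts Random elemental starts per trimmed regression.
#' @param seed Integer seed controlling the random starts.
#' @return A [decomposition()] with `method = "arf"`.
#' @export
arf <- function(W, t = 0.75, intercept = FALSE, max_iter = 100L,
                tol = 1e-8, n_starts = 20L, seed = 1L) {
  stopifnot(inherits(W, "fitness_matrix"))
  stopifnot(t > 0.5, t <= 1)
  v <- unclass(W)
  n <- nrow(v); m <- ncol(v)
  if (!any(rowSums(!is.na(v)) >= 2L))
    stop("cannot decompose: no row with at least 2 non-missing entries")

  old_rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()), add = TRUE)
  set.seed(seed)

  y <- as.numeric(svd_init(W))
  x <- rep(NA_real_, n)
  for (it in seq_len(max_iter)) {
    x_old <- x; y_old <- y
    for (a in seq_len(n)) {
      use <- !is.na(v[a, ]) & !is.na(y)
      fit <- if (sum(use) >= 2L)
        lts_fit(y[use], v[a, use], t = t, intercept = intercept,
                n_starts = n_starts) else NULL
      x[a] <- if (is.null(fit)) NA_real_ else fit$slope
    }
    for (b in seq_len(m)) {
      use <- !is.na(v[, b]) & !is.na(x)
      fit <- if (sum(use) >= 2L)
        lts_fit(x[use], v[use, b], t = t, intercept = intercept,
                n_starts = n_starts) else NULL
      y[b] <- if (is.null(fit)) NA_real_ else fit$slope
    }
    nrm <- sqrt(sum(y[!is.na(y)]^2))
    if (nrm < .EPISCREEN_ZERO_TOL)
      stop("degenerate decomposition: query factor collapsed to zero")
    y <- y / nrm
    x <- x * nrm
    delta <- c(x, y) - c(x_old, y_old)
    ok <- !is.na(delta)
    if (it > 1L && all(!is.na(c(x_old, y_old))[ok])) {
      rel <- abs(delta[ok]) / pmax(abs(c(x_old, y_old))[ok], 1e-8)
      if (length(rel) && max(rel) < tol) break
    }
  }

  names(x) <- array_ids(W); names(y) <- query_ids(W)
  decomposition(x, y, method = "arf",
                params = list(t = t, intercept = intercept,
                              max_iter = max_iter, tol = tol,
                              n_starts = n_starts, seed = seed))
}
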