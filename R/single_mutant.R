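#' Fix the sign of a rank-one decomposition
#'
#' Alternating fitting can converge to factors with all elements negative;
#' the rank-one fit is unchanged under joint negation, but the array factor
#' is later interpreted as a fitness scale. If the median of the defined
#' array components is negative, both factors are multiplied by -1.
#'
#' @param dec A [decomposition()].
#' @return The decomposition with a nonnegative array-factor median.
#' @export
fix_sign <- function(dec) {
  stopifnot(inherits(dec, "decomposition"))
  xs <- dec$x[dec$x_defined]
  if (length(xs) && stats::median(xs) < 0) {
    dec$x <- -dec$x
    dec$y <- -dec$y
  }
  dec
}

#' Single-mutant fitness estimates from a decomposition
#'
#' The factors of a rank-one decomposition are unique only up to scale. A
#' unique single-mutant fitness vector `w` is obtained by scaling the unit
#' array factor with the mutants shared between the array and query sets:
#' with `xh`, `yh` the unit-length normalizations of the defined parts of
#' `x` and `y`, `M` is the median of the nonnegative ratios `yh[j]/xh[j]`
#' over the shared mutants `j`, and
#' `w = sqrt(M * ||x|| * ||y||) * xh`, so that `w[a] * w[b]` equals the
#' rank-one fitted value `x[a] * y[b]` wherever `yh` is proportional to
#' `xh` with factor `M`.
#'
#' @param dec A [decomposition()] (sign-fixed first; see [fix_sign()]).
#' @param W The [fitness_matrix()] the decomposition came from (supplies
#'   the identifier sets).
#' @return An object of class `single_mutant_fitness`: list with `w`
#'   (named numeric, `NA` where the array component is undefined), the
#'   scaling constant `M`, `kappa` (the per-column correction constant
#'   `sqrt(M ||x|| ||y||)/||x||`), and `shared_ids`.
#' @export
scale_single_mutant_fitness <- function(dec, W) {
  stopifnot(inherits(dec, "decomposition"), inherits(W, "fitness_matrix"))
  x <- dec$x; y <- dec$y
  nx <- sqrt(sum(x[dec$x_defined]^2))
  ny <- sqrt(sum(y[dec$y_defined]^2))
  if (nx < .EPISCREEN_ZERO_TOL || ny < .EPISCREEN_ZERO_TOL)
    stop("cannot scale: a factor has zero norm")
  xh <- x / nx; yh <- y / ny

  shared <- intersect(names(x)[dec$x_defined], names(y)[dec$y_defined])
  if (length(shared) == 0L)
    stop("cannot scale: no mutant is shared between arrays and queries")
  ratios <- yh[shared] / xh[shared]
  ratios <- ratios[is.finite(ratios) & ratios >= 0]
  if (length(ratios) == 0L)
    stop("cannot scale: all shared-mutant ratios are negative")
  M <- stats::median(ratios)

  w <- sqrt(M * nx * ny) * xh
  structure(list(w = w, M = M, kappa = sqrt(M * nx * ny) / nx,
                 shared_ids = shared),
            class = "single_mutant_fitness")
}

#' @export
print.single_mutant_fitness <- function(x, ...) {
  cat(sprintf(
    "single-mutant fitness estimates: %d mutants (%d defined), M = %.4g\n",
    length(x$w), sum(!is.na(x$w)), x$M))
  invisible(x)
}

#' Correct between-screen technical variation
#'
#' Each query screen (column of W) carries its own technical factor; the
#' query vector `y` of the decomposition estimates it. The correction
#' rescales column b by `kappa * w_q[b] / y[b]`, where `w_q[b]` is the
#' single-mutant fitness estimate of query b looked up by identifier and
#' `kappa = sqrt(M ||x|| ||y||)/||x||`. Under the exact multiplicative
#' null the corrected matrix equals the outer product `w %o% w_q`, so any
#' per-column screen effect cancels exactly. Entries in columns whose
#' query factor is below the zero tolerance, undefined, or whose query has
#' no fitness estimate become missing.
#'
#' @param W A [fitness_matrix()] (the same matrix the decomposition was
#'   fitted to, or its restriction to shared queries).
#' @param dec The [decomposition()].
#' @param smf The [scale_single_mutant_fitness()] result.
#' @return The corrected `fitness_matrix`.
#' @export
correct_screen_effects <- function(W, dec, smf) {
  stopifnot(inherits(W, "fitness_matrix"),
            inherits(dec, "decomposition"),
            inherits(smf, "single_mutant_fitness"))
  v <- unclass(W)
  qids <- query_ids(W)
  y <- dec$y[qids]
  wq <- smf$w[qids]
  fac <- smf$kappa * wq / y
  fac[is.na(y) | abs(y) < .EPISCREEN_ZERO_TOL | is.na(wq)] <- NA_real_
  out <- sweep(v, 2L, fac, `*`)
  fitness_matrix(out, array_ids(W), qids)
}
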