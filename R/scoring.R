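#' Interaction score for one gene pair
#'
#' Scores a gene pair from its (corrected) double-mutant fitness `w_ab`
#' and the two single-mutant fitness estimates `w_a`, `w_b`, as the
#' residual against a null model of non-interaction:
#' \describe{
#'   \item{minimum}{`w_ab - min(w_a, w_b)`}
#'   \item{maximum}{`w_ab - max(w_a, w_b)`}
#'   \item{product}{`e = w_ab - w_a * w_b` (the multiplicative-null
#'     residual, the conventional epistasis measure)}
#'   \item{scaled_epistasis}{the product residual normalized by its
#'     extreme value: `e / (w_a * w_b)` for `e < 0` (so a synthetic-lethal
#'     pair with `w_ab = 0` scores exactly -1) and
#'     `e / (min(w_a, w_b) - w_a * w_b)` for `e > 0` (so a double mutant
#'     as fit as the less-fit single mutant scores +1). The positive
#'     branch diverges when one single mutant is near wild type, so the
#'     score is truncated at +/-1000; when the denominator magnitude is
#'     below 1e-12 the truncation value is returned with the sign of `e`.
#'     Undefined when `w_a * w_b <= 0`.}
#' }
#' All inputs are recycled to a common length.
#'
#' @param w_ab Corrected double-mutant fitness value(s).
#' @param w_a,w_b Single-mutant fitness estimates.
#' @param fn Scoring function tag.
#' @return Numeric score(s); `NA` where undefined.
#' @examples
#' score_pair(0.2, 0.8, 0.5, "product")           # -0.2
#' score_pair(0, 0.8, 0.5, "scaled_epistasis")    # -1: synthetic lethal
#' @export
score_pair <- function(w_ab, w_a, w_b,
                       fn = c("minimum", "maximum", "product",
                              "scaled_epistasis")) {
  fn <- match.arg(fn)
  len <- max(length(w_ab), length(w_a), length(w_b))
  w_ab <- rep_len(w_ab, len); w_a <- rep_len(w_a, len)
  w_b <- rep_len(w_b, len)
  undef <- is.na(w_a) | is.na(w_b)
  out <- switch(fn,
    minimum = w_ab - pmin(w_a, w_b),
    maximum = w_ab - pmax(w_a, w_b),
    product = w_ab - w_a * w_b,
    scaled_epistasis = {
      prod_ <- w_a * w_b
      e <- w_ab - prod_
      denom <- ifelse(e < 0, prod_, pmin(w_a, w_b) - prod_)
      s <- ifelse(e == 0, 0, e / denom)
      tiny <- !is.na(denom) & abs(denom) < 1e-12 & !is.na(e) & e != 0
      s[tiny] <- sign(e[tiny]) * 1000
      s <- pmin(pmax(s, -1000), 1000)
      s[!is.na(prod_) & prod_ <= 0] <- NA_real_
      s
    })
  out[undef | is.na(w_ab)] <- NA_real_
  out
}

#' Build the interaction score matrix
#'
#' Applies a scoring function entry-wise to a corrected fitness matrix
#' restricted to shared-query columns, pairing each entry's double-mutant
#' fitness with the single-mutant estimates of its array and query
#' mutants. Scores are missing where the input entry is missing, where a
#' single-mutant estimate is undefined, or where the score itself is
#' undefined. A query identifier with no fitness estimate yields a fully
#' missing column and a warning.
#'
#' @param W_corrected The screen-corrected [fitness_matrix()] (shared
#'   queries only; see [restrict_to_shared_queries()] and
#'   [correct_screen_effects()]).
#' @param smf The [scale_single_mutant_fitness()] result covering the
#'   array identifiers.
#' @param fn Scoring function tag as in [score_pair()].
#' @param provenance Optional provenance list stored on the result.
#' @return A [score_matrix()] with the same shape and identifiers as
#'   `W_corrected`.
#' @export
build_score_matrix <- function(W_corrected, smf,
                               fn = c("minimum", "maximum", "product",
                                      "scaled_epistasis"),
                               provenance = list()) {
  fn <- match.arg(fn)
  stopifnot(inherits(W_corrected, "fitness_matrix"),
            inherits(smf, "single_mutant_fitness"))
  v <- unclass(W_corrected)
  aids <- array_ids(W_corrected); qids <- query_ids(W_corrected)
  wa <- smf$w[aids]
  wq <- smf$w[qids]
  missing_q <- qids[is.na(wq)]
  if (length(missing_q))
    warning("no single-mutant fitness estimate for query ",
            paste(missing_q, collapse = ", "),
            "; the corresponding columns are fully missing")
  s <- matrix(NA_real_, nrow(v), ncol(v))
  for (b in seq_len(ncol(v)))
    s[, b] <- score_pair(v[, b], wa, wq[b], fn)
  score_matrix(s, aids, qids, scoring_function = fn,
               provenance = provenance)
}
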