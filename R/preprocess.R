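#' Location-shift preprocessing of a fitness matrix
#'
#' Three optional location-shift removals that can be applied to a
#' double-mutant fitness matrix before decomposition: subtraction of row
#' means, column means, or the grand mean. Means are computed over the
#' non-missing entries only; the missingness mask is never altered. Rows or
#' columns with no observed entries are returned unchanged.
#'
#' @param W A [fitness_matrix()].
#' @return A `fitness_matrix` of the same shape with the shift removed.
#' @seealso [apply_preprocessing()] for the config-driven dispatcher.
#' @export
subtract_row_means <- function(W) {
  stopifnot(inherits(W, "fitness_matrix"))
  v <- unclass(W)
  mu <- rowMeans(v, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0  # all-missing rows stay unchanged
  fitness_matrix(v - mu, array_ids(W), query_ids(W))
}

#' @rdname subtract_row_means
#' @export
subtract_col_means <- function(W) {
  stopifnot(inherits(W, "fitness_matrix"))
  v <- unclass(W)
  mu <- colMeans(v, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  fitness_matrix(sweep(v, 2L, mu), array_ids(W), query_ids(W))
}

#' @rdname subtract_row_means
#' @export
subtract_grand_mean <- function(W) {
  stopifnot(inherits(W, "fitness_matrix"))
  v <- unclass(W)
  if (all(is.na(v))) stop("cannot compute grand mean: all entries missing")
  fitness_matrix(v - mean(v, na.rm = TRUE), array_ids(W), query_ids(W))
}

#' @rdname subtract_row_means
#' @param method One of `"none"`, `"row_mean"`, `"col_mean"`,
#'   `"grand_mean"`.
#' @export
apply_preprocessing <- function(W, method = c("none", "row_mean",
                                              "col_mean", "grand_mean")) {
  method <- match.arg(method)
  switch(method,
         none = W,
         row_mean = subtract_row_means(W),
         col_mean = subtract_col_means(W),
         grand_mean = subtract_grand_mean(W))
}
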