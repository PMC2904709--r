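#' Double-mutant fitness matrix
#'
#' Container for an n x m double-mutant fitness matrix W, with rows indexed
#' by array mutants and columns by query mutants. Missing (filtered or
#' unmeasured) entries are carried as a logical mask; the corresponding
#' values are `NA`. Identifiers are uppercased on construction so that yeast
#' ORF names match across sources regardless of case.
#'
#' @param values Numeric matrix (n x m). Non-finite entries other than `NA`
#'   are rejected; `NA` entries are flagged missing.
#' @param array_ids Character vector of n unique row (array mutant) ids.
#'   Defaults to `rownames(values)`.
#' @param query_ids Character vector of m unique column (query mutant) ids.
#'   Defaults to `colnames(values)`.
#' @param missing Optional logical matrix (n x m); entries flagged `TRUE`
#'   are treated as missing in addition to `NA` values.
#' @return An object of class `fitness_matrix`: a numeric matrix with
#'   dimnames set to the identifiers and `NA` at missing entries.
#' @examples
#' W <- fitness_matrix(matrix(c(1, 2, 2, 4), 2, 2),
#'                     array_ids = c("YAL001C", "YBR123W"),
#'                     query_ids = c("YAL001C", "YBR123W"))
#' dim(W)
#' @export
fitness_matrix <- function(values, array_ids = rownames(values),
                           query_ids = colnames(values), missing = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  n <- nrow(values); m <- ncol(values)
  if (is.null(array_ids) || is.null(query_ids))
    stop("array and query identifiers are required")
  array_ids <- toupper(as.character(array_ids))
  query_ids <- toupper(as.character(query_ids))
  if (length(array_ids) != n || length(query_ids) != m)
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(array_ids))
    stop("duplicate array identifier: ",
         paste(unique(array_ids[duplicated(array_ids)]), collapse = ", "))
  if (anyDuplicated(query_ids))
    stop("duplicate query identifier: ",
         paste(unique(query_ids[duplicated(query_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (!is.null(missing)) {
    if (!is.logical(missing) || !identical(dim(missing), dim(values)))
      stop("'missing' must be a logical matrix with the same dimensions")
    values[missing] <- NA_real_
  }
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-finite entries must be flagged missing")
  dimnames(values) <- list(array_ids, query_ids)
  class(values) <- c("fitness_matrix", class(values))
  values
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat(sprintf("fitness_matrix: %d array x %d query mutants, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname fitness_matrix
#' @param x A `fitness_matrix`.
#' @export
array_ids <- function(x) rownames(x)

#' @rdname fitness_matrix
#' @export
query_ids <- function(x) colnames(x)

#' @rdname fitness_matrix
#' @export
missing_mask <- function(x) is.na(unclass(x))

#' Interaction score matrix
#'
#' A score matrix S with the same shape and identifiers as the fitness
#' matrix it was derived from, holding per-pair interaction scores
#' (model residuals) instead of fitness measurements.
#'
#' @param values Numeric matrix of scores, `NA` where missing or undefined.
#' @param array_ids,query_ids Identifiers as in [fitness_matrix()].
#' @param scoring_function One of `"minimum"`, `"maximum"`, `"product"`,
#'   `"scaled_epistasis"`.
#' @param provenance Optional list recording the decomposition method and
#'   parameters the scores were computed under.
#' @return An object of class `score_matrix` (also a `fitness_matrix`).
#' @export
score_matrix <- function(values, array_ids = rownames(values),
                         query_ids = colnames(values),
                         scoring_function, provenance = list()) {
  scoring_function <- match.arg(scoring_function,
                                c("minimum", "maximum", "product",
                                  "scaled_epistasis"))
  out <- fitness_matrix(values, array_ids, query_ids)
  attr(out, "scoring_function") <- scoring_function
  attr(out, "provenance") <- provenance
  class(out) <- c("score_matrix", class(out))
  out
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "score_matrix (%s): %d array x %d query mutants, %.1f%% missing\n",
    attr(x, "scoring_function"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a fitness matrix from tab-separated text
#'
#' Expects a header row of query identifiers, a first column of array
#' identifiers, tab delimiters, `.` as the decimal separator and `NA`
#' (or an empty cell) as the missing token.
#'
#' @param path Path to the TSV file.
#' @return A [fitness_matrix()].
#' @export
read_fitness_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  m <- length(header) - 1L
  if (m < 0L) stop("malformed header in ", path)
  query_ids <- header[-1L]
  body <- fields[-1L]
  n <- length(body)
  vals <- matrix(NA_real_, n, m)
  arr <- character(n)
  for (i in seq_len(n)) {
    row <- body[[i]]
    # trailing missing cells may be dropped by line splitting
    if (length(row) < m + 1L && length(row) >= 1L)
      row <- c(row, rep("", m + 1L - length(row)))
    if (length(row) != m + 1L)
      stop(sprintf("ragged row %d: expected %d cells, found %d",
                   i, m + 1L, length(row) - 1L))
    arr[i] <- row[1L]
    cells <- row[-1L]
    miss <- cells == "NA" | cells == ""
    parsed <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(parsed))
    if (length(bad))
      stop(sprintf("unparseable cell at row '%s', column '%s': '%s'",
                   row[1L], query_ids[bad[1L]], cells[bad[1L]]))
    parsed[miss] <- NA_real_
    vals[i, ] <- parsed
  }
  fitness_matrix(vals, array_ids = arr, query_ids = query_ids)
}

#' Write a fitness or score matrix as tab-separated text
#'
#' Serializes with 15 significant digits so that a read/write round trip
#' preserves values to at least 12 significant digits; missing entries are
#' written as `NA`.
#'
#' @param matrix_ A `fitness_matrix` or `score_matrix`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fitness_tsv <- function(matrix_, path) {
  stopifnot(inherits(matrix_, "fitness_matrix"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(paste(c("", query_ids(matrix_)), collapse = "\t"), con)
  if (nrow(matrix_) > 0L) {
    if (ncol(matrix_) == 0L) {
      writeLines(array_ids(matrix_), con)
    } else {
      body <- matrix(sprintf("%.15g", unclass(matrix_)), nrow(matrix_))
      body[is.na(unclass(matrix_))] <- "NA"
      writeLines(paste(array_ids(matrix_),
                       apply(body, 1L, paste, collapse = "\t"),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_fitness_tsv
#' @export
write_score_tsv <- write_fitness_tsv

#' Restrict a matrix to columns whose query is also an array mutant
#'
#' Single-mutant fitness estimates come from the array vector, so scoring
#' and evaluation use only the sub-matrix in which each query mutant also
#' occurs among the array mutants; column order is preserved.
#'
#' @param W A `fitness_matrix`.
#' @return The restricted `fitness_matrix`.
#' @export
restrict_to_shared_queries <- function(W) {
  stopifnot(inherits(W, "fitness_matrix"))
  keep <- query_ids(W) %in% array_ids(W)
  if (!any(keep))
    stop("no shared mutants: no query identifier occurs among the array ids")
  out <- unclass(W)[, keep, drop = FALSE]
  fitness_matrix(out, array_ids = array_ids(W),
                 query_ids = query_ids(W)[keep])
}
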