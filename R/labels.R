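.EPISCREEN_CATEGORIES <- c("SL", "SS", "PE", "PS")

#' Catalog of known genetic interaction pairs
#'
#' Holds the four BioGRID genetic interaction categories as sets of
#' unordered gene pairs: synthetic lethality (SL), synthetic growth
#' defect / synthetic sick (SS), phenotypic enhancement (PE) and
#' phenotypic suppression (PS). Pairs are stored with uppercased
#' identifiers sorted within the pair; self-pairs are dropped.
#'
#' @param SL,SS,PE,PS Two-column character matrices or data frames of
#'   gene-identifier pairs (may be empty).
#' @param source_version Free-text provenance of the pair sets.
#' @return An object of class `interaction_catalog`: a list of four
#'   character vectors of canonical `"ID1|ID2"` pair keys.
#' @export
interaction_catalog <- function(SL = NULL, SS = NULL, PE = NULL, PS = NULL,
                                source_version = "") {
  canon <- function(p) {
    if (is.null(p) || NROW(p) == 0L) return(character(0))
    p <- as.matrix(p)
    a <- toupper(as.character(p[, 1L]))
    b <- toupper(as.character(p[, 2L]))
    keep <- a != b
    unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]),
                 sep = "|"))
  }
  structure(list(SL = canon(SL), SS = canon(SS), PE = canon(PE),
                 PS = canon(PS), source_version = source_version),
            class = "interaction_catalog")
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat(sprintf("interaction catalog%s: SL=%d SS=%d PE=%d PS=%d pairs\n",
              if (nzchar(x$source_version))
                paste0(" (", x$source_version, ")") else "",
              length(x$SL), length(x$SS), length(x$PE), length(x$PS)))
  invisible(x)
}

#' Parse a BioGRID-style tab-delimited interaction file
#'
#' Accepts either the BioGRID TAB 2.0 layout (columns located by the
#' header names "Systematic Name Interactor A/B" and "Experimental
#' System") or a simplified headerless 3-column TSV (idA, idB, category).
#' Rows whose experimental system matches (case-insensitively) one of
#' "Synthetic Lethality", "Synthetic Growth Defect", "Phenotypic
#' Enhancement" or "Phenotypic Suppression" are assigned to the SL, SS,
#' PE, PS sets respectively; all other rows (physical interaction systems,
#' Synthetic Rescue, ...) are skipped.
#'
#' @param path Path to the tab-delimited file.
#' @param aliases Optional two-column data frame mapping gene symbols to
#'   systematic ORF names, applied to the interactor columns before
#'   canonicalization.
#' @param source_version Free-text version tag stored on the catalog.
#' @return An [interaction_catalog()].
#' @export
parse_biogrid_tab <- function(path, aliases = NULL, source_version = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  header <- as.character(unlist(tab[1L, ], use.names = FALSE))
  find_col <- function(pat) {
    hit <- grep(pat, header, ignore.case = TRUE)
    if (length(hit)) hit[1L] else NA_integer_
  }
  ca <- find_col("^Systematic Name Interactor A$")
  cb <- find_col("^Systematic Name Interactor B$")
  cs <- find_col("^Experimental System$")
  if (!is.na(ca) && !is.na(cb) && !is.na(cs)) {
    tab <- tab[-1L, , drop = FALSE]
  } else if (ncol(tab) == 3L) {
    ca <- 1L; cb <- 2L; cs <- 3L
  } else {
    stop("missing required columns: need 'Systematic Name Interactor A/B'",
         " and 'Experimental System', or a 3-column (idA, idB, category)",
         " table")
  }
  a <- toupper(as.character(tab[[ca]]))
  b <- toupper(as.character(tab[[cb]]))
  if (!is.null(aliases)) {
    al <- stats::setNames(toupper(as.character(aliases[[2L]])),
                          toupper(as.character(aliases[[1L]])))
    a <- ifelse(a %in% names(al), al[a], a)
    b <- ifelse(b %in% names(al), al[b], b)
  }
  system_ <- tolower(trimws(as.character(tab[[cs]])))
  sets <- list(
    SL = cbind(a, b)[system_ == "synthetic lethality", , drop = FALSE],
    SS = cbind(a, b)[system_ == "synthetic growth defect", , drop = FALSE],
    PE = cbind(a, b)[system_ == "phenotypic enhancement", , drop = FALSE],
    PS = cbind(a, b)[system_ == "phenotypic suppression", , drop = FALSE])
  interaction_catalog(SL = sets$SL, SS = sets$SS, PE = sets$PE,
                      PS = sets$PS, source_version = source_version)
}

#' Label the entries of a score matrix for one interaction category
#'
#' Produces one labelled item per non-missing, non-self entry of the
#' matrix: label 1 iff the unordered pair {array id, query id} belongs to
#' the chosen category's set, label 0 otherwise — including pairs in the
#' other categories, since the complement of each category serves as its
#' neutral reference set.
#'
#' @param S A [score_matrix()] (or any `fitness_matrix`).
#' @param catalog An [interaction_catalog()].
#' @param category One of `"SL"`, `"SS"`, `"PE"`, `"PS"`.
#' @return List with `labels` (integer 0/1), `scores` (the matching score
#'   values) and `entry_index` (two-column matrix of row/col indices).
#'   Signals a condition of class `episcreen_no_positives` when the
#'   category has no positive among the labelled entries.
#' @export
label_entries <- function(S, catalog,
                          category = c("SL", "SS", "PE", "PS")) {
  category <- match.arg(category)
  stopifnot(inherits(S, "fitness_matrix"),
            inherits(catalog, "interaction_catalog"))
  v <- unclass(S)
  aids <- array_ids(S); qids <- query_ids(S)
  idx <- which(!is.na(v), arr.ind = TRUE)
  a <- aids[idx[, 1L]]; b <- qids[idx[, 2L]]
  keep <- a != b  # self-pairs excluded
  idx <- idx[keep, , drop = FALSE]
  a <- a[keep]; b <- b[keep]
  key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  labels <- as.integer(key %in% catalog[[category]])
  if (!any(labels == 1L))
    stop(structure(class = c("episcreen_no_positives", "error",
                             "condition"),
                   list(message = paste0("no positives: no non-missing ",
                                         "entry belongs to category ",
                                         category),
                        call = sys.call(-1L))))
  list(labels = labels, scores = v[idx], entry_index = idx)
}
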