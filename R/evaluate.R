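#' ROC curve of a labelled score set
#'
#' Sweeps the discrimination threshold over the distinct score values and
#' returns the ROC vertices (FPR, TPR). Tied scores are grouped into a
#' single vertex, so the curve cuts diagonally across blocks of ties
#' (equivalent to half-credit for tied pairs in the area). The `polarity`
#' says which end of the score scale is category-like: with
#' `"low_scores_positive"` the ranking is reversed before the sweep.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length.
#' @param polarity `"high_scores_positive"` or `"low_scores_positive"`.
#' @return Two-column matrix of vertices with columns `fpr`, `tpr`,
#'   starting at (0, 0) and ending at (1, 1), both nondecreasing.
#' @export
roc_curve <- function(scores, labels,
                      polarity = c("high_scores_positive",
                                   "low_scores_positive")) {
  polarity <- match.arg(polarity)
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC requires at least one positive and one negative label")
  if (polarity == "low_scores_positive") scores <- -scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)  # last index of each tie group
  tp <- cumsum(l)[last]; fp <- (last - cumsum(l)[last])
  cbind(fpr = c(0, fp / N), tpr = c(0, tp / P))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under a tie-grouped ROC curve; equals the normalized
#' Mann-Whitney statistic with ties counted one half.
#'
#' @param roc Vertex matrix from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  f <- roc[, 1L]; t <- roc[, 2L]
  sum(diff(f) * (t[-1L] + t[-length(t)]) / 2)
}

#' Standardized partial area under the ROC curve
#'
#' Trapezoidal area of the ROC curve over FPR in \[0, fpr_max\], with
#' linear interpolation at the cap; if `standardized`, divided by
#' `fpr_max` so that a perfect classifier scores 1 (and the chance level
#' is `fpr_max / 2` divided by `fpr_max`, i.e. 0.5... at `fpr_max = 1`
#' the standardized value equals the AUC).
#'
#' @param roc Vertex matrix from [roc_curve()].
#' @param fpr_max FPR cap in (0, 1].
#' @param standardized Divide by the maximal attainable area `fpr_max`.
#' @return Partial area.
#' @export
partial_auc <- function(roc, fpr_max = 0.5, standardized = TRUE) {
  stopifnot(fpr_max > 0, fpr_max <= 1)
  f <- roc[, 1L]; t <- roc[, 2L]
  keep <- f <= fpr_max
  fc <- f[keep]; tc <- t[keep]
  if (max(fc) < fpr_max) {
    fc <- c(fc, fpr_max)
    tc <- c(tc, sensitivity_at_fpr(roc, fpr_max))
  }
  area <- sum(diff(fc) * (tc[-1L] + tc[-length(tc)]) / 2)
  if (standardized) area / fpr_max else area
}

#' Sensitivity at a fixed false positive rate
#'
#' TPR of the ROC curve at the given FPR, linearly interpolated between
#' adjacent vertices; at a vertical jump the upper envelope is taken.
#'
#' @param roc Vertex matrix from [roc_curve()].
#' @param fpr Target FPR in \[0, 1\].
#' @return TPR in \[0, 1\].
#' @export
sensitivity_at_fpr <- function(roc, fpr = 0.10) {
  stopifnot(fpr >= 0, fpr <= 1)
  f <- roc[, 1L]; t <- roc[, 2L]
  i <- max(which(f <= fpr))
  if (f[i] == fpr) return(max(t[f == fpr]))
  frac <- (fpr - f[i]) / (f[i + 1L] - f[i])
  t[i] + frac * (t[i + 1L] - t[i])
}

#' Specificity at a fixed true positive rate
#'
#' 1 - FPR at the first point of the ROC curve where TPR reaches the
#' target, with the FPR linearly interpolated along the crossing segment.
#'
#' @param roc Vertex matrix from [roc_curve()].
#' @param tpr Target TPR in \[0, 1\].
#' @return Specificity in \[0, 1\].
#' @export
specificity_at_tpr <- function(roc, tpr = 0.70) {
  stopifnot(tpr >= 0, tpr <= 1)
  f <- roc[, 1L]; t <- roc[, 2L]
  i <- which(t >= tpr)[1L]
  if (is.na(i)) return(0)
  if (i == 1L || t[i] == tpr && f[i] < f[i - 1L]) return(1 - f[i])
  if (t[i] == t[i - 1L]) return(1 - f[i - 1L])
  frac <- (tpr - t[i - 1L]) / (t[i] - t[i - 1L])
  1 - (f[i - 1L] + frac * (f[i] - f[i - 1L]))
}

#' Evaluate one interaction category against its complement
#'
#' Labels the non-missing, non-self entries of the score matrix with
#' [label_entries()] and computes the ROC curve plus the four accuracy
#' metrics: overall AUC, standardized partial AUC at the FPR cap,
#' sensitivity at a fixed FPR and specificity at a fixed TPR. Phenotypic
#' suppression (PS), the positive-interaction class, is ranked with the
#' most positive scores first; the three negative classes (SL, SS, PE)
#' with the most negative scores first.
#'
#' @param S A [score_matrix()] (or a raw `fitness_matrix` for baseline
#'   ranking).
#' @param catalog An [interaction_catalog()].
#' @param category One of `"SL"`, `"SS"`, `"PE"`, `"PS"`.
#' @param fpr_max FPR cap for the standardized partial AUC (default 0.5).
#' @param sens_fpr FPR at which sensitivity is read off (default 0.10).
#' @param spec_tpr TPR at which specificity is read off (default 0.70).
#' @param polarity Ranking orientation; defaults by category as above.
#' @return An object of class `evaluation_result`: list with `roc`,
#'   `auc`, `pauc`, `sens_at_fpr`, `spec_at_tpr`, `category`, `polarity`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_category <- function(S, catalog,
                              category = c("SL", "SS", "PE", "PS"),
                              fpr_max = 0.5, sens_fpr = 0.10,
                              spec_tpr = 0.70, polarity = NULL) {
  category <- match.arg(category)
  if (is.null(polarity))
    polarity <- if (category == "PS") "high_scores_positive"
                else "low_scores_positive"
  lab <- label_entries(S, catalog, category)
  roc <- roc_curve(lab$scores, lab$labels, polarity)
  structure(list(roc = roc,
                 auc = auc(roc),
                 pauc = partial_auc(roc, fpr_max, standardized = TRUE),
                 sens_at_fpr = sensitivity_at_fpr(roc, sens_fpr),
                 spec_at_tpr = specificity_at_tpr(roc, spec_tpr),
                 category = category, polarity = polarity,
                 n_pos = sum(lab$labels == 1L),
                 n_neg = sum(lab$labels == 0L)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("%s (%d pos / %d neg): AUC %.3f, pAUC %.3f, ",
                     "sens@FPR %.3f, spec@TPR %.3f\n"),
              x$category, x$n_pos, x$n_neg, x$auc, x$pauc,
              x$sens_at_fpr, x$spec_at_tpr))
  invisible(x)
}

#' Default quantile-parameter grid
#'
#' @param by Grid step for both p and q.
#' @return Data frame of (p, q) combinations.
#' @export
default_qma_grid <- function(by = 0.05) {
  g <- seq(0.05, 0.95, by = by)
  expand.grid(p = g, q = g, KEEP.OUT.ATTRS = FALSE)
}

#' Select QMA quantile parameters on a labelled matrix
#'
#' Runs the full transformation (decompose, sign-fix, scale, restrict to
#' shared queries, correct, score, evaluate) for every grid point and
#' returns the (p, q) maximizing the mode's objective: mean AUC over all
#' four categories (`fixed`), AUC on PS (`adjusted_positive`), or mean
#' AUC over SL, SS and PE (`adjusted_negative`). Ties are broken by the
#' smaller p, then the smaller q. Grid points at which the evaluation
#' fails (no shared mutants, no positives, ...) are skipped.
#'
#' @param W A [fitness_matrix()].
#' @param catalog An [interaction_catalog()].
#' @param mode `"fixed"`, `"adjusted_positive"` or `"adjusted_negative"`.
#' @param grid Data frame with columns `p` and `q`.
#' @param scoring_positive,scoring_negative Scoring-function tags used
#'   for the PS and the SL/SS/PE categories respectively.
#' @param preprocessing Preprocessing option applied before each
#'   decomposition (see [apply_preprocessing()]).
#' @param ... Further arguments passed to [evaluate_category()].
#' @return List with `p`, `q`, `objective` and the per-grid-point
#'   objective table (`trace`).
#' @export
adjust_parameters <- function(W, catalog,
                              mode = c("fixed", "adjusted_positive",
                                       "adjusted_negative"),
                              grid = default_qma_grid(),
                              scoring_positive = "product",
                              scoring_negative = "minimum",
                              preprocessing = "none", ...) {
  mode <- match.arg(mode)
  stopifnot(nrow(grid) > 0L)
  cats <- switch(mode,
                 fixed = c("SL", "SS", "PE", "PS"),
                 adjusted_positive = "PS",
                 adjusted_negative = c("SL", "SS", "PE"))
  Wp <- apply_preprocessing(W, preprocessing)
  objective <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    aucs <- tryCatch({
      dec <- fix_sign(qma(Wp, grid$p[i], grid$q[i]))
      smf <- scale_single_mutant_fitness(dec, Wp)
      Wr <- restrict_to_shared_queries(Wp)
      Wc <- correct_screen_effects(Wr, dec, smf)
      vapply(cats, function(cc) {
        fn <- if (cc == "PS") scoring_positive else scoring_negative
        S <- suppressWarnings(build_score_matrix(Wc, smf, fn))
        evaluate_category(S, catalog, cc, ...)$auc
      }, numeric(1L))
    }, error = function(e) NULL)
    if (!is.null(aucs)) objective[i] <- mean(aucs)
  }
  if (all(is.na(objective)))
    stop("parameter adjustment failed at every grid point")
  ord <- order(-objective, grid$p, grid$q, na.last = TRUE)
  best <- ord[1L]
  list(p = grid$p[best], q = grid$q[best], objective = objective[best],
       mode = mode,
       trace = cbind(grid, objective = objective))
}
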