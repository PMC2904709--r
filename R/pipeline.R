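#' Shipped parameter presets
#'
#' Recommended quantile parameters, preprocessing option and scoring
#' functions for the three screen technologies, in fixed mode (one
#' parameter set for all four categories) and in the modes adjusted to
#' the positive (PS) or the negative (SL/SS/PE) categories.
#'
#' @param name Preset name, `"<dataset>.<mode>"` with dataset one of
#'   `sga`, `gim`, `emap` and mode one of `fixed`, `adjusted_p`,
#'   `adjusted_n` (e.g. `"sga.fixed"`).
#' @return A config list understood by [run_pipeline()].
#' @examples
#' preset("sga.fixed")$qma   # p = 0.55, q = 0.95
#' @export
preset <- function(name) {
  presets <- list(
    sga.fixed       = list(p = 0.55, q = 0.95, preprocessing = "none",
                           positive = "product", negative = "minimum"),
    sga.adjusted_p  = list(p = 0.10, q = 0.95, preprocessing = "none",
                           positive = "product", negative = "minimum"),
    sga.adjusted_n  = list(p = 0.95, q = 0.50, preprocessing = "none",
                           positive = "product", negative = "minimum"),
    gim.fixed       = list(p = 0.60, q = 0.50, preprocessing = "none",
                           positive = "minimum",
                           negative = "scaled_epistasis"),
    gim.adjusted_p  = list(p = 0.05, q = 0.95, preprocessing = "none",
                           positive = "maximum",
                           negative = "scaled_epistasis"),
    gim.adjusted_n  = list(p = 0.80, q = 0.25, preprocessing = "none",
                           positive = "minimum",
                           negative = "scaled_epistasis"),
    emap.fixed      = list(p = 0.50, q = 0.60, preprocessing = "row_mean",
                           positive = "minimum", negative = "minimum"),
    emap.adjusted_p = list(p = 0.30, q = 0.65, preprocessing = "row_mean",
                           positive = "minimum", negative = "minimum"),
    emap.adjusted_n = list(p = 0.50, q = 0.15, preprocessing = "row_mean",
                           positive = "minimum", negative = "minimum"))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  list(method = "qma",
       preprocessing = p$preprocessing,
       qma = list(p = p$p, q = p$q),
       scoring = list(positive = p$positive, negative = p$negative),
       eval = list(fpr_max = 0.5, sens_fpr = 0.10, spec_tpr = 0.70),
       preset = name)
}

.default_config <- function() {
  list(method = "qma",
       preprocessing = "none",
       qma = list(p = 0.5, q = 0.5),
       arf = list(t = 0.75, intercept = FALSE, max_iter = 100L,
                  tol = 1e-8, n_starts = 20L, seed = 1L),
       scoring = list(positive = "product", negative = "minimum"),
       eval = list(fpr_max = 0.5, sens_fpr = 0.10, spec_tpr = 0.70))
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full data transformation and evaluation pipeline
#'
#' Executes the stages in fixed order: preprocessing, rank-one
#' decomposition of the (full) matrix, sign fixing, scaling of the array
#' factor to single-mutant fitness estimates, restriction to
#' shared-query columns, screen-effect correction, scoring with the
#' configured positive and negative scoring functions, and — when an
#' interaction catalog is supplied — ROC evaluation of the four
#' categories (PS with the positive function, SL/SS/PE with the negative
#' function). The run is a pure function of the inputs, the config and
#' the seed.
#'
#' @param W A [fitness_matrix()] or a path to a fitness TSV.
#' @param catalog An [interaction_catalog()], a path to a BioGRID-style
#'   file, or `NULL` (evaluation skipped with a warning).
#' @param config Config list; missing entries take defaults. Start from
#'   [preset()] for the shipped parameter combinations. Keys: `method`
#'   ("qma"/"arf"), `preprocessing`, `qma$p`, `qma$q`, `arf$t`,
#'   `arf$intercept`, `arf$max_iter`, `arf$tol`, `arf$n_starts`,
#'   `arf$seed`, `scoring$positive`, `scoring$negative`, `eval$fpr_max`,
#'   `eval$sens_fpr`, `eval$spec_tpr`.
#' @param output_dir Optional directory; when given, the config, the
#'   factor vectors, the score matrices and the evaluation report are
#'   written there.
#' @return List with `decomposition`, `w` (the single-mutant fitness
#'   estimates), `corrected` (the corrected shared-query matrix),
#'   `score_matrices` (one per distinct scoring function), `evaluations`
#'   (per category) and `report` (a data frame mirroring the evaluation
#'   tables: one row per category with the four metrics).
#' @export
run_pipeline <- function(W, catalog = NULL, config = list(),
                         output_dir = NULL) {
  cfg <- .merge_config(.default_config(), config)
  if (is.character(W)) W <- read_fitness_tsv(W)
  if (is.character(catalog)) catalog <- parse_biogrid_tab(catalog)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  Wp <- stage("preprocess", apply_preprocessing(W, cfg$preprocessing))
  dec <- stage("decompose", switch(cfg$method,
    qma = qma(Wp, cfg$qma$p, cfg$qma$q),
    arf = arf(Wp, t = cfg$arf$t, intercept = cfg$arf$intercept,
              max_iter = cfg$arf$max_iter, tol = cfg$arf$tol,
              n_starts = cfg$arf$n_starts, seed = cfg$arf$seed),
    stop("unknown method '", cfg$method, "'")))
  dec <- fix_sign(dec)
  smf <- stage("scale", scale_single_mutant_fitness(dec, Wp))
  Wr <- stage("restrict", restrict_to_shared_queries(Wp))
  Wc <- stage("correct", correct_screen_effects(Wr, dec, smf))

  fns <- unique(c(cfg$scoring$positive, cfg$scoring$negative))
  scores <- stage("score", {
    out <- lapply(fns, function(fn)
      build_score_matrix(Wc, smf, fn,
                         provenance = list(method = cfg$method,
                                           params = dec$params)))
    stats::setNames(out, fns)
  })

  evaluations <- NULL; report <- NULL
  if (is.null(catalog)) {
    warning("no interaction catalog supplied; evaluation skipped")
  } else {
    evaluations <- stage("evaluate", {
      out <- lapply(.EPISCREEN_CATEGORIES, function(cc) {
        fn <- if (cc == "PS") cfg$scoring$positive else cfg$scoring$negative
        evaluate_category(scores[[fn]], catalog, cc,
                          fpr_max = cfg$eval$fpr_max,
                          sens_fpr = cfg$eval$sens_fpr,
                          spec_tpr = cfg$eval$spec_tpr)
      })
      stats::setNames(out, .EPISCREEN_CATEGORIES)
    })
    report <- do.call(rbind, lapply(evaluations, function(ev)
      data.frame(category = ev$category,
                 scoring_function = attr(
                   scores[[if (ev$category == "PS") cfg$scoring$positive
                           else cfg$scoring$negative]],
                   "scoring_function"),
                 n_pos = ev$n_pos, n_neg = ev$n_neg,
                 sens_at_fpr = ev$sens_at_fpr,
                 spec_at_tpr = ev$spec_at_tpr,
                 pauc = ev$pauc, auc = ev$auc)))
    rownames(report) <- NULL
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(output_dir, "config.yaml"))
    write_vec <- function(v, path)
      utils::write.table(
        data.frame(id = names(v), value = sprintf("%.15g", v)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_vec(dec$x, file.path(output_dir, "array_factor_x.tsv"))
    write_vec(dec$y, file.path(output_dir, "query_factor_y.tsv"))
    write_vec(smf$w, file.path(output_dir, "single_mutant_fitness_w.tsv"))
    for (fn in names(scores))
      write_score_tsv(scores[[fn]],
                      file.path(output_dir, paste0("scores_", fn, ".tsv")))
    if (!is.null(report))
      utils::write.table(report, file.path(output_dir, "evaluation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(decomposition = dec, w = smf, corrected = Wc,
       score_matrices = scores, evaluations = evaluations,
       report = report, config = cfg)
}
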