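#' Design of a synthetic genetic interaction screen
#'
#' Parameters of the generator in [generate_screen()]. The defaults give
#' a desk-scale screen with the statistical structure the decomposition
#' assumes: a multiplicative null, per-screen technical factors,
#' non-normal (log-normal) multiplicative noise, around 10% missingness
#' and rare planted interactions.
#'
#' @param n_arrays Number of array mutants (rows).
#' @param n_queries Number of query mutants (columns).
#' @param shared_fraction Fraction of queries that are also array mutants
#'   (query strains are typically a subset of the array collection).
#' @param missing_rate Expected fraction of missing entries, in \[0, 1).
#' @param missing_mechanism `"uniform"` or `"fitness_dependent"` (lower
#'   fitness values are more likely to be filtered, logistic in the
#'   value).
#' @param noise_sigma Scale of the log-normal multiplicative noise.
#' @param screen_factor_range Length-2 positive range for the per-query
#'   technical factors.
#' @param interaction_rates Named numeric vector: fraction of entries
#'   planted per category (names among SL, SS, PE, PS; must sum to
#'   < 0.5).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `screen_design`.
#' @export
screen_design <- function(n_arrays = 200L, n_queries = 80L,
                          shared_fraction = 1.0, missing_rate = 0.10,
                          missing_mechanism = c("uniform",
                                                "fitness_dependent"),
                          noise_sigma = 0.1,
                          screen_factor_range = c(0.8, 1.25),
                          interaction_rates = c(SL = 0.005, SS = 0.005,
                                                PE = 0.005, PS = 0.005),
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_arrays >= 2L, n_queries >= 1L,
            shared_fraction > 0, shared_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            noise_sigma >= 0,
            length(screen_factor_range) == 2L,
            all(screen_factor_range > 0),
            all(names(interaction_rates) %in% .EPISCREEN_CATEGORIES),
            all(interaction_rates >= 0),
            sum(interaction_rates) < 0.5,
            round(n_queries * shared_fraction) >= 1)
  structure(list(n_arrays = as.integer(n_arrays),
                 n_queries = as.integer(n_queries),
                 shared_fraction = shared_fraction,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 noise_sigma = noise_sigma,
                 screen_factor_range = screen_factor_range,
                 interaction_rates = interaction_rates,
                 seed = as.integer(seed)),
            class = "screen_design")
}

#' Generate a synthetic double-mutant fitness screen
#'
#' Simulates a screen under the multiplicative null with planted
#' interactions of the four categories. Single-mutant fitness values are
#' drawn from a two-component mixture (90% near wild type, uniform on
#' 0.85-1.05; 10% sick, uniform on 0.3-0.85). Null entries are
#' `w_a * w_b * g_b * exp(sigma * Z)` with a per-query screen factor
#' `g_b` and standard-normal `Z`. Planted entries replace the null:
#' synthetic-lethal pairs are 0; synthetic-sick pairs are the null scaled
#' by c ~ U(0.05, 0.4); phenotypic-enhancement pairs by c ~ U(0.5, 0.8);
#' phenotypic-suppression pairs are `min(w_a, w_b) * (1 + u)` (u ~
#' U(0.1, 0.5)) times screen factor and noise, i.e. fitter than either
#' single mutant predicts. Missingness is then applied uniformly at
#' random, or with probability increasing as the entry value decreases
#' (`"fitness_dependent"`).
#'
#' @param design A [screen_design()].
#' @return List with `W` (a [fitness_matrix()]) and `truth` (class
#'   `synthetic_truth`: `w_true` for every mutant, `screen_factors`
#'   per query, and `planted`, a per-category list of two-column
#'   array/query id matrices).
#' @export
generate_screen <- function(design = screen_design()) {
  stopifnot(inherits(design, "screen_design"))
  old_rng <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, globalenv()), add = TRUE)
  set.seed(design$seed)

  n <- design$n_arrays; m <- design$n_queries
  n_shared <- round(m * design$shared_fraction)
  if (n_shared > n) stop("more shared queries than array mutants")
  array_ids <- sprintf("ARR%04d", seq_len(n))
  query_ids <- c(sample(array_ids, n_shared),
                 if (m > n_shared) sprintf("QRY%04d", seq_len(m - n_shared)))

  all_ids <- union(array_ids, query_ids)
  sick <- stats::runif(length(all_ids)) < 0.10
  w_true <- ifelse(sick, stats::runif(length(all_ids), 0.3, 0.85),
                   stats::runif(length(all_ids), 0.85, 1.05))
  names(w_true) <- all_ids

  g <- stats::runif(m, design$screen_factor_range[1L],
                    design$screen_factor_range[2L])
  names(g) <- query_ids

  noise <- function(k) exp(design$noise_sigma * stats::rnorm(k))
  wa <- w_true[array_ids]; wq <- w_true[query_ids]
  W <- outer(wa, wq) * rep(g, each = n) * matrix(noise(n * m), n, m)

  # plant interactions on distinct non-self cells
  eligible <- which(outer(array_ids, query_ids, `!=`))
  rates <- design$interaction_rates
  n_plant <- round(rates * n * m)
  n_plant <- pmin(n_plant, length(eligible))
  planted <- list()
  pool <- sample(eligible)
  off <- 0L
  for (cat in names(n_plant)) {
    k <- n_plant[[cat]]
    cells <- pool[seq_len(k) + off]
    off <- off + k
    a <- (cells - 1L) %% n + 1L
    b <- (cells - 1L) %/% n + 1L
    null_ab <- w_true[array_ids[a]] * w_true[query_ids[b]] * g[b]
    W[cells] <- switch(cat,
      SL = 0,
      SS = stats::runif(k, 0.05, 0.4) * null_ab * noise(k),
      PE = stats::runif(k, 0.5, 0.8) * null_ab * noise(k),
      PS = pmin(w_true[array_ids[a]], w_true[query_ids[b]]) *
           (1 + stats::runif(k, 0.1, 0.5)) * g[b] * noise(k))
    planted[[cat]] <- cbind(array = array_ids[a], query = query_ids[b])
  }

  if (design$missing_rate > 0) {
    if (design$missing_mechanism == "uniform") {
      p_miss <- rep(design$missing_rate, n * m)
    } else {
      # logistic in the entry value: low-fitness entries filtered more
      raw <- stats::plogis(-(W - stats::median(W)) /
                             max(stats::sd(W), 1e-8))
      p_miss <- pmin(design$missing_rate * raw / mean(raw), 1)
    }
    W[stats::runif(n * m) < p_miss] <- NA_real_
  }

  truth <- structure(list(w_true = w_true, screen_factors = g,
                          planted = planted),
                     class = "synthetic_truth")
  list(W = fitness_matrix(W, array_ids, query_ids), truth = truth)
}

#' Export planted interaction pairs as an interaction catalog
#'
#' Allows the evaluation machinery to run unchanged on synthetic screens,
#' using the planted pairs as ground truth.
#'
#' @param truth A `synthetic_truth` from [generate_screen()].
#' @return An [interaction_catalog()].
#' @export
truth_catalog <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$planted
  interaction_catalog(SL = p$SL, SS = p$SS, PE = p$PE, PS = p$PS,
                      source_version = "synthetic ground truth")
}
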