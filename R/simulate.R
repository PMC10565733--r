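#' Three-component Gaussian model of pairwise CC distributions
#'
#' The calibration simulation models pairwise intensity correlations between
#' chunk data sets of two structures A and B with three Gaussian components:
#' within-A, within-B and between-A/B, each parameterised by a median
#' (location) and standard deviation. The reference parameters, fitted to
#' apo/benzamidine-bound trypsin chunk data, are medians
#' 0.978 / 0.970 / 0.962 with SDs 0.020 / 0.019 / 0.017.
#'
#' @param within_a,within_b,between Length-2 numeric vectors
#'   `c(median, sd)`; defaults are the reference trypsin fit.
#' @param dcc_fit_cutoff d_CC cutoff used when fitting the model from
#'   observed CCs (default 0.4; see [fit_cc_model()]).
#' @return An object of class `cc_model`.
#' @export
cc_model <- function(within_a = c(0.978, 0.020),
                     within_b = c(0.970, 0.019),
                     between = c(0.962, 0.017),
                     dcc_fit_cutoff = 0.4) {
  comp <- function(x, nm) {
    if (length(x) != 2 || !all(is.finite(x))) {
      abort_config(paste0(nm, " must be c(median, sd)"))
    }
    if (abs(x[1]) >= 1) abort_config(paste0(nm, " median must lie in (-1, 1)"))
    if (x[2] < 0) abort_config(paste0(nm, " sd must be >= 0"))
    list(median = x[1], sd = x[2])
  }
  structure(
    list(within_a = comp(within_a, "within_a"),
         within_b = comp(within_b, "within_b"),
         between = comp(between, "between"),
         dcc_fit_cutoff = dcc_fit_cutoff),
    class = "cc_model"
  )
}

#' @export
print.cc_model <- function(x, ...) {
  cat(sprintf(paste0("<cc_model> within_a %.4g (sd %.3g), within_b %.4g (sd %.3g), ",
                     "between %.4g (sd %.3g)\n"),
              x$within_a$median, x$within_a$sd, x$within_b$median,
              x$within_b$sd, x$between$median, x$between$sd))
  invisible(x)
}

#' Fit the CC-distribution model from observed pairwise CCs
#'
#' Each sample set is first restricted to its prominent peak by the d_CC
#' filter: only CCs with `sqrt(1 - CC^2) < dcc_fit_cutoff` (CC > ~0.9165 at
#' the default cutoff 0.4) enter the fit, which removes the low-CC tail of
#' poor chunks. The per-set median and standard deviation of the survivors
#' parameterise the model.
#'
#' @param cc_within_a,cc_within_b,cc_between Numeric vectors of observed
#'   pairwise CCs.
#' @param dcc_fit_cutoff d_CC filter cutoff (default 0.4).
#' @return A [cc_model()].
#' @export
fit_cc_model <- function(cc_within_a, cc_within_b, cc_between,
                         dcc_fit_cutoff = 0.4) {
  cc_min <- sqrt(1 - dcc_fit_cutoff^2)
  fit1 <- function(x, nm) {
    x <- x[!is.na(x) & x > cc_min]
    if (length(x) == 0) {
      abort_data(paste0("no ", nm, " CCs survive the d_CC < ",
                        dcc_fit_cutoff, " filter"))
    }
    c(median(x), if (length(x) > 1) sd(x) else 0)
  }
  cc_model(within_a = fit1(cc_within_a, "within_a"),
           within_b = fit1(cc_within_b, "within_b"),
           between = fit1(cc_between, "between"),
           dcc_fit_cutoff = dcc_fit_cutoff)
}

#' Sample a synthetic CC distance matrix from the model
#'
#' Draws one CC per unordered chunk pair from the Gaussian of its pair class
#' (within-A, within-B or between), clips to `[-(1-1e-6), 1-1e-6]`, and
#' transforms to distances. Pairs are sampled independently; the matrix is
#' symmetric with zero diagonal but not constrained to be positive
#' semi-definite (hierarchical clustering only needs pairwise
#' dissimilarities).
#'
#' @param model A [cc_model()].
#' @param n_a,n_b Group sizes (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @param metric Distance transform, see [cc_to_distance()].
#' @return An `iso_dist` whose labels are `A1..A<n_a>, B1..B<n_b>`, with the
#'   true group of each label in attribute `groups`.
#' @export
sample_cc_matrix <- function(model, n_a, n_b, seed = NULL,
                             metric = "sqrt_one_minus_cc2") {
  if (!inherits(model, "cc_model")) abort_config("`model` must be a cc_model")
  if (n_a < 2 || n_b < 2) abort_config("group sizes must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  n <- n_a + n_b
  grp <- rep(c(1L, 2L), c(n_a, n_b))
  pair_class <- outer(grp, grp, function(g1, g2) ifelse(g1 == g2, g1, 3L))
  med <- c(model$within_a$median, model$within_b$median, model$between$median)
  sds <- c(model$within_a$sd, model$within_b$sd, model$between$sd)
  iu <- which(upper.tri(pair_class))
  cc <- matrix(1, n, n)
  draws <- rnorm(length(iu), med[pair_class[iu]], sds[pair_class[iu]])
  cc[iu] <- pmin(pmax(draws, -(1 - 1e-6)), 1 - 1e-6)
  cc[lower.tri(cc)] <- t(cc)[lower.tri(cc)]
  D <- cc_to_distance(cc, metric)
  diag(D) <- 0
  labels <- c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)))
  out <- new_iso_dist(labels = labels, values = D, metric = metric, cc = cc)
  attr(out, "groups") <- stats::setNames(c(rep("A", n_a), rep("B", n_b)), labels)
  out
}

#' Replicated HCA simulation on sampled CC matrices
#'
#' The core of the threshold calibration: for each replicate, sample a CC
#' matrix from the model, run Ward clustering, record the root height `W0`,
#' the larger child-of-root height `W1`, their ratio, and the two-cut
#' classification score against the true group labels. Child seeds are drawn
#' deterministically from the master seed, so a run is fully reproducible.
#'
#' @param model A [cc_model()].
#' @param n_a,n_b Group sizes; the defaults 42/41 mirror the 83 chunks
#'   retained in the reference trypsin analysis.
#' @param replicates Number of replicates (default 100).
#' @param seed Master seed.
#' @param metric,method Distance transform and linkage (defaults d_CC, Ward).
#' @return A tibble of class `cc_sim` with columns `replicate`, `W0`, `W1`,
#'   `R_obs`, `score`.
#' @export
run_simulation <- function(model, n_a = 42, n_b = 41, replicates = 100,
                           seed = 1, metric = "sqrt_one_minus_cc2",
                           method = "ward") {
  if (replicates < 1) abort_config("replicates must be >= 1")
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, replicates)
  rows <- purrr::map(seq_len(replicates), function(r) {
    D <- sample_cc_matrix(model, n_a, n_b, seed = child_seeds[r],
                          metric = metric)
    tree <- linkage_cluster(D, method = method)
    tibble(replicate = r, W0 = tree$W0, W1 = tree$W1,
           R_obs = if (tree$W0 > 0) tree$W1 / tree$W0 else 0,
           score = classification_score(tree, attr(D, "groups"), k = 2))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cc_sim", class(out))
  attr(out, "model") <- model
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  attr(out, "seed") <- seed
  out
}

#' @method glance cc_sim
#' @export
glance.cc_sim <- function(x, ...) {
  tibble(replicates = nrow(x),
         mean_W0 = mean(x$W0), mean_W1 = mean(x$W1), sd_W1 = sd(x$W1),
         mean_R = mean(x$R_obs), mean_score = mean(x$score),
         min_score = min(x$score), frac_perfect = mean(x$score == 1))
}

#' Overlap sweep: degrade the model until classification fails
#'
#' Starting from the fitted model, the between-structure median is moved
#' linearly towards the within-B median in `steps` steps (step 0 is the
#' unmodified model; at the final step the two components coincide and
#' classification must fail). For each step and each total data-set count in
#' `n_list` (split into two balanced groups), [run_simulation()] is run and
#' the mean observed ratio `R = W1/W0` and mean classification score are
#' recorded. The sweep traces how far the threshold ratio can be pushed
#' before classification breaks down.
#'
#' @param model A [cc_model()].
#' @param steps Number of interpolation steps (>= 2, default 10).
#' @param n_list Total data-set counts (default `c(100, 200, 300, 500,
#'   1000)`).
#' @param replicates Replicates per grid point (default 20).
#' @param seed Master seed.
#' @return A tibble of class `cc_sweep` with columns `overlap_step`,
#'   `n_datasets`, `between_median`, `mean_R`, `mean_score`, `sd_score`,
#'   `mean_W0`, `mean_W1`.
#' @export
approach_sweep <- function(model, steps = 10,
                           n_list = c(100, 200, 300, 500, 1000),
                           replicates = 20, seed = 1) {
  if (!inherits(model, "cc_model")) abort_config("`model` must be a cc_model")
  if (steps < 2) abort_config("steps must be >= 2")
  if (replicates < 1) abort_config("replicates must be >= 1")
  set.seed(seed)
  grid_seeds <- matrix(sample.int(.Machine$integer.max, steps * length(n_list)),
                       nrow = steps)
  grid <- tidyr::expand_grid(overlap_step = seq_len(steps) - 1L,
                             n_datasets = n_list)
  rows <- purrr::pmap(grid, function(overlap_step, n_datasets) {
    f <- overlap_step / (steps - 1)
    m_s <- cc_model(
      within_a = c(model$within_a$median, model$within_a$sd),
      within_b = c(model$within_b$median, model$within_b$sd),
      between = c(model$between$median +
                    f * (model$within_b$median - model$between$median),
                  model$between$sd),
      dcc_fit_cutoff = model$dcc_fit_cutoff
    )
    n_a <- ceiling(n_datasets / 2)
    sim <- run_simulation(m_s, n_a = n_a, n_b = n_datasets - n_a,
                          replicates = replicates,
                          seed = grid_seeds[overlap_step + 1,
                                            match(n_datasets, n_list)])
    tibble(overlap_step = overlap_step, n_datasets = n_datasets,
           between_median = m_s$between$median,
           mean_R = mean(sim$R_obs), mean_score = mean(sim$score),
           sd_score = sd(sim$score),
           mean_W0 = mean(sim$W0), mean_W1 = mean(sim$W1))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cc_sweep", class(out))
  attr(out, "model") <- model
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  out
}

#' Recommend the isomorphic threshold ratio from a sweep
#'
#' Restricts the sweep to grid points with `n_datasets <= n_max` ("several
#' hundred data sets") and mean classification score at or above
#' `score_threshold`, and returns the range of mean observed ratios
#' `R = W1/W0` over those points: the interval of ratios at which
#' classification still succeeds.
#'
#' @param sweep A `cc_sweep` from [approach_sweep()].
#' @param score_threshold Score regarded as successful classification
#'   (default 0.9).
#' @param n_max Largest data-set count considered (default 500).
#' @return Named numeric vector `c(R_low = , R_high = )`.
#' @export
recommend_ratio <- function(sweep, score_threshold = 0.9, n_max = 500) {
  if (!inherits(sweep, "cc_sweep") || nrow(sweep) == 0) {
    abort_config("`sweep` must be a non-empty cc_sweep")
  }
  ok <- sweep$n_datasets <= n_max & sweep$mean_score >= score_threshold
  if (!any(ok)) {
    abort_data(sprintf(
      "no sweep point with n <= %d reaches mean score %.3g: classification fails at all tested ratios",
      n_max, score_threshold))
  }
  r <- range(sweep$mean_R[ok])
  c(R_low = r[1], R_high = r[2])
}

#' Sweep results as a ggplot
#'
#' Classification score against observed ratio `R = W1/W0`, one line per
#' data-set count, with the success threshold drawn as a dotted line.
#'
#' @param object A `cc_sweep`.
#' @param score_threshold Threshold line to draw (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_sweep
#' @export
autoplot.cc_sweep <- function(object, score_threshold = 0.9, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_R, y = .data$mean_score,
                               colour = factor(.data$n_datasets))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = score_threshold, linetype = "dotted") +
    ggplot2::labs(x = "R = W1 / W0", y = "classification score",
                  colour = "data sets") +
    ggplot2::theme_minimal()
}
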