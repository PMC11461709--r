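#' Weighted Gaussian kernel density estimate
#'
#' KDE of a weighted sample with Silverman's rule-of-thumb bandwidth
#' computed on the weighted sample (effective sample size in place of n).
#' A degenerate sample (single distinct value) falls back to a small
#' positive bandwidth so the density remains proper.
#'
#' @param samples Numeric sample values.
#' @param weights Non-negative weights (uniform if `NULL`).
#' @param grid Evaluation grid (default: range widened by 4 bandwidths,
#'   `n_grid` points).
#' @param n_grid Grid size when `grid` is `NULL`.
#' @param bw Bandwidth override.
#' @return A tibble with columns `x` and `density` (integrates to 1 on its
#'   grid up to truncation error).
#' @export
weighted_kde <- function(samples, weights = NULL, grid = NULL, n_grid = 512,
                         bw = NULL) {
  n <- length(samples)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights) == 0) abort("all weights are zero")
  w <- weights / sum(weights)
  if (is.null(bw)) {
    mu <- sum(w * samples)
    sdw <- sqrt(sum(w * (samples - mu)^2))
    qs <- weighted_quantile(samples, w, c(0.25, 0.75))
    iqr <- qs[2] - qs[1]
    neff <- 1 / sum(w^2)
    spread <- min(sdw, iqr / 1.34)
    if (!is.finite(spread) || spread <= 0) spread <- max(sdw, 1e-8)
    bw <- 0.9 * spread * neff^(-1 / 5)
    if (!is.finite(bw) || bw <= 0)
      bw <- max(abs(mu) * 1e-3, 1e-8)  # point-mass fallback
  }
  if (is.null(grid))
    grid <- seq(min(samples) - 4 * bw, max(samples) + 4 * bw,
                length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, samples, bw)), numeric(1))
  tibble(x = grid, density = dens)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Maximum a posteriori estimate from a weighted ensemble
#'
#' Per-parameter marginal mode: the argmax of each parameter's weighted
#' Gaussian KDE on a 512-point grid, with ties broken toward the smaller
#' value. (A per-coordinate marginal MAP, not the joint mode; recorded in
#' the result's `method` attribute.)
#'
#' @param x An `"abc_fit"` object or a tibble/matrix of parameter columns.
#' @param weights Weights (taken from the fit if `x` is an `abc_fit`).
#' @param n_grid KDE grid size.
#' @return Named numeric vector of marginal modes.
#' @export
map_estimate <- function(x, weights = NULL, n_grid = 512) {
  if (inherits(x, "abc_fit")) {
    weights <- x$particles$weight
    x <- x$particles[x$prior$name]
  }
  m <- as_qoi_matrix(x)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  out <- vapply(seq_len(ncol(m)), function(j) {
    k <- weighted_kde(m[, j], weights, n_grid = n_grid)
    k$x[which.max(k$density)]  # first max = smaller value on ascending grid
  }, numeric(1))
  structure(setNames(out, colnames(m)), method = "marginal_kde_mode")
}

#' Posterior predictive check
#'
#' Draws parameters from the weighted ensemble, simulates datasets for
#' each draw, and compares the pooled simulated QoI marginals against the
#' observed data: per QoI, means, standard deviations and quantiles of
#' both, plus the raw pooled simulations for plotting.
#'
#' @param fit An `"abc_fit"` object (or tibble of parameters with a
#'   `weight` column).
#' @param simulator Function `(theta, m, seed) -> QoI matrix`.
#' @param y_obs_qois Observed QoI tibble/matrix.
#' @param n_draws Posterior draws.
#' @param m_prime Simulations per draw.
#' @param seed Seed (deterministic output).
#' @return A tibble of class `"predictive_check"` with one row per QoI and
#'   attribute `sim_qois` (pooled simulated QoI tibble).
#' @export
predictive_check <- function(fit, simulator, y_obs_qois, n_draws = 100,
                             m_prime = 25, seed = 1) {
  set.seed(seed)
  if (inherits(fit, "abc_fit")) {
    theta <- as_qoi_matrix(fit$particles[fit$prior$name])
    w <- fit$particles$weight
  } else {
    theta <- as_qoi_matrix(fit[setdiff(names(fit), c("weight", "distance"))])
    w <- fit$weight
  }
  y_obs <- as_qoi_matrix(y_obs_qois)
  draw_idx <- sample.int(nrow(theta), n_draws, replace = TRUE, prob = w)
  seeds <- sample.int(.Machine$integer.max - 1, n_draws)
  sims <- purrr::map2(draw_idx, seeds, function(i, s) {
    y <- simulator(theta[i, ], m_prime, s)
    if (is.null(y)) NULL else as_qoi_matrix(y)
  })
  sims <- do.call(rbind, sims[!vapply(sims, is.null, logical(1))])
  if (is.null(sims) || nrow(sims) == 0) abort("all predictive simulations failed")
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  summarise_col <- function(v, prefix) {
    out <- c(mean(v), sd(v), quantile(v, qs))
    setNames(out, paste0(prefix, c("_mean", "_sd", paste0("_q", qs * 100))))
  }
  rows <- purrr::map(seq_len(ncol(y_obs)), function(j) {
    c(summarise_col(y_obs[, j], "data"), summarise_col(sims[, j], "sim"))
  })
  out <- dplyr::bind_cols(
    tibble(qoi = colnames(y_obs)),
    as_tibble(do.call(rbind, rows))
  )
  attr(out, "sim_qois") <- as_tibble(sims)
  attr(out, "data_qois") <- as_tibble(y_obs)
  class(out) <- c("predictive_check", class(out))
  out
}

#' Pair observed and simulated neurons in QoI space
#'
#' Normalises both QoI clouds by the observed data's marginal standard
#' deviations and assigns to each data row the nearest simulated row
#' (Euclidean distance, with replacement).
#'
#' @param data_qois,sim_qois QoI tibbles/matrices with identical columns.
#' @return A tibble with columns `data_row`, `sim_row`, `distance`.
#' @export
pair_neurons <- function(data_qois, sim_qois) {
  dm <- as_qoi_matrix(data_qois)
  sm <- as_qoi_matrix(sim_qois)
  if (ncol(dm) != ncol(sm)) abort("column count mismatch")
  if (nrow(dm) == 0 || nrow(sm) == 0) abort("empty point cloud")
  stats <- qoi_standardization(dm)
  dstd <- as_qoi_matrix(standardize(dm, stats))
  sstd <- as_qoi_matrix(standardize(sm, stats))
  nn <- FNN::get.knnx(sstd, dstd, k = 1)
  tibble(data_row = seq_len(nrow(dm)),
         sim_row = as.integer(nn$nn.index[, 1]),
         distance = nn$nn.dist[, 1])
}

#' Anderson-Darling normality check of QoI marginals
#'
#' Tests each QoI column against the normal family with estimated
#' parameters and reports the decision at the requested level.
#'
#' @param qoi_matrix QoI tibble/matrix with at least 8 rows.
#' @param level Significance level for the `reject` decision.
#' @return A tibble with columns `qoi`, `statistic`, `p_value`, `reject`.
#' @export
marginal_normality_check <- function(qoi_matrix, level = 0.01) {
  m <- as_qoi_matrix(qoi_matrix)
  if (nrow(m) < 8) abort("need at least 8 rows")
  if (is.null(colnames(m))) colnames(m) <- paste0("q", seq_len(ncol(m)))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (sd(v) == 0) abort(sprintf("constant column: %s", colnames(m)[j]))
    tst <- nortest::ad.test(v)
    tibble(qoi = colnames(m)[j], statistic = unname(tst$statistic),
           p_value = tst$p.value, reject = tst$p.value < level)
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic SWC + QoI fixture on disk
#'
#' Simulates `m` neurons, writes one SWC file per neuron plus a `qois.csv`
#' table, fully reproducible from `seed`. This generator stands in for
#' observed datasets in all tests and examples.
#'
#' @param params A [model_params()] object.
#' @param m Number of neurons.
#' @param out_dir Output directory (created if missing).
#' @param seed Root seed.
#' @param selection QoI subtree selection for the CSV.
#' @param init,field As in [simulate_neuron()].
#' @return The QoI tibble, invisibly; files land in `out_dir`.
#' @export
generate_fixture <- function(params, m, out_dir, seed = 1,
                             selection = c("all", "apical", "basal"),
                             init = NULL, field = guidance_field()) {
  selection <- match.arg(selection)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- simulate_dataset(params, m, init = init, field = field, seed = seed)
  paths <- file.path(out_dir, sprintf("neuron_%04d.swc", seq_len(m)))
  purrr::walk2(trees, paths, write_swc)
  qois <- dataset_qois(trees, selection)
  write_qois(qois, file.path(out_dir, "qois.csv"))
  invisible(qois)
}
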