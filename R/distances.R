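#' Column standardisation statistics
#'
#' Center/scale statistics computed from an observed QoI matrix, applied
#' to both observed and simulated clouds before a distance is evaluated so
#' that heterogeneous units (counts vs. lengths) contribute comparably.
#'
#' @param x QoI tibble or matrix.
#' @return A tibble of class `"standardization_stats"` with columns
#'   `column`, `center`, `scale`.
#' @export
qoi_standardization <- function(x) {
  m <- as_qoi_matrix(x)
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(!is.finite(scl)) || any(scl <= 0))
    abort("zero-variance column: cannot standardize",
          class = "abcgrow_zero_scale")
  structure(
    tibble(column = colnames(m), center = ctr, scale = scl),
    class = c("standardization_stats", class(tibble()))
  )
}

#' Standardise a QoI matrix
#'
#' @param x QoI tibble or matrix.
#' @param stats A [qoi_standardization()] object (typically computed from
#'   the observed data).
#' @return A tibble with `(value - center) / scale` per column.
#' @export
standardize <- function(x, stats) {
  m <- as_qoi_matrix(x)
  if (ncol(m) != nrow(stats)) abort("column count mismatch")
  out <- sweep(sweep(m, 2, stats$center, "-"), 2, stats$scale, "/")
  as_tibble(out)
}

#' Exact 2-Wasserstein distance between QoI point clouds
#'
#' Distance between the uniform empirical measures on the rows of `x` and
#' `y` under the Euclidean ground metric, order p = 2, computed by solving
#' the discrete optimal transport problem exactly (successive shortest
#' augmenting paths; 1-D inputs use the closed-form quantile coupling).
#' Cardinalities may differ; the solver requires `lcm(n, m)` transport
#' units, so cardinalities should share a large common divisor.
#'
#' @param x,y QoI tibbles or numeric matrices with equal column counts.
#' @return Non-negative scalar; zero iff the multisets coincide.
#' @examples
#' wasserstein_distance(matrix(c(0, 1)), matrix(c(1, 2)))
#' @export
wasserstein_distance <- function(x, y) {
  mx <- as_qoi_matrix(x); my <- as_qoi_matrix(y)
  if (ncol(mx) != ncol(my)) abort("column count mismatch")
  if (nrow(mx) == 0 || nrow(my) == 0) abort("empty point cloud")
  if (ncol(mx) == 1) return(sqrt(cpp_w2sq_1d(mx[, 1], my[, 1])))
  sqrt(cpp_w2sq(mx, my))
}

#' Sliced 2-Wasserstein distance
#'
#' Root-mean of squared 1-D Wasserstein distances over random unit
#' projection directions. Uses R's RNG for the projections; seed with
#' [set.seed()] for reproducibility.
#'
#' @inheritParams wasserstein_distance
#' @param n_projections Number of random directions.
#' @return Non-negative scalar.
#' @export
sliced_wasserstein_distance <- function(x, y, n_projections = 50) {
  mx <- as_qoi_matrix(x); my <- as_qoi_matrix(y)
  if (ncol(mx) != ncol(my)) abort("column count mismatch")
  if (nrow(mx) == 0 || nrow(my) == 0) abort("empty point cloud")
  d <- ncol(mx)
  pr <- matrix(rnorm(d * n_projections), d)
  pr <- sweep(pr, 2, sqrt(colSums(pr^2)), "/")
  px <- mx %*% pr
  py <- my %*% pr
  w2 <- vapply(seq_len(n_projections),
               function(j) cpp_w2sq_1d(px[, j], py[, j]), numeric(1))
  sqrt(mean(w2))
}

# nearest-neighbour radii used by the divergence estimators; exact
# coincidences (within-set self matches, or duplicated points across
# sets) are treated as ties and broken toward the next neighbour, with a
# 1e-12 floor guarding genuine duplicates
nn_radii <- function(x, y = NULL, jitter = 1e-12) {
  if (is.null(y)) {
    r <- FNN::get.knn(x, k = 1)$nn.dist[, 1]
  } else {
    nn <- FNN::get.knnx(y, x, k = min(2L, nrow(y)))
    r <- nn$nn.dist[, 1]
    if (ncol(nn$nn.dist) > 1) {
      tie <- r <= jitter
      r[tie] <- nn$nn.dist[tie, 2]
    }
  }
  pmax(r, jitter)
}

#' k-nearest-neighbour estimate of the Kullback-Leibler divergence
#'
#' 1-NN estimator of `KL(P_x || P_y)` from samples: the mean log-ratio of
#' nearest-neighbour radii (in `y` vs. within `x`) scaled by the dimension
#' plus the `log(m / (n - 1))` correction. Asymmetric; may be negative at
#' small sample sizes (estimates are passed through unmodified so that
#' threshold comparisons remain meaningful). Duplicate points are guarded
#' by a 1e-12 radius floor.
#'
#' @inheritParams wasserstein_distance
#' @return Scalar estimate (any sign).
#' @export
kl_divergence_knn <- function(x, y) {
  mx <- as_qoi_matrix(x); my <- as_qoi_matrix(y)
  if (ncol(mx) != ncol(my)) abort("column count mismatch")
  n <- nrow(mx); m <- nrow(my); d <- ncol(mx)
  if (n < 2 || m < 2) abort("need at least 2 points per cloud")
  r <- nn_radii(mx)        # within x, self excluded
  s <- nn_radii(mx, my)    # from x into y
  d * mean(log(s / r)) + log(m / (n - 1))
}

#' k-nearest-neighbour estimate of the gamma-divergence
#'
#' Plug-in estimate of the Fujisawa-Eguchi gamma-divergence using 1-NN
#' density estimates in the gamma-cross-entropy terms. Approaches the
#' [kl_divergence_knn()] estimate as `gamma -> 0`; larger `gamma` damps
#' the influence of outliers.
#'
#' @inheritParams wasserstein_distance
#' @param gamma Positive robustness parameter.
#' @return Scalar estimate (any sign).
#' @export
gamma_divergence <- function(x, y, gamma = 0.5) {
  stopifnot(gamma > 0)
  mx <- as_qoi_matrix(x); my <- as_qoi_matrix(y)
  if (ncol(mx) != ncol(my)) abort("column count mismatch")
  n <- nrow(mx); m <- nrow(my); d <- ncol(mx)
  if (n < 2 || m < 2) abort("need at least 2 points per cloud")
  vd <- pi^(d / 2) / base::gamma(d / 2 + 1)  # unit-ball volume
  g_at_x <- 1 / ((n - 1) * vd * nn_radii(mx)^d)
  f_at_x <- 1 / (m * vd * nn_radii(mx, my)^d)
  f_at_y <- 1 / ((m - 1) * vd * nn_radii(my)^d)
  lme <- function(v) {  # log mean exp(gamma * log v), stabilised
    lv <- gamma * log(v)
    mx0 <- max(lv)
    mx0 + log(mean(exp(lv - mx0)))
  }
  lme(g_at_x) / (gamma * (1 + gamma)) - lme(f_at_x) / gamma +
    lme(f_at_y) / (1 + gamma)
}

#' Build a distance function from configuration keys
#'
#' @param name One of `"wasserstein"`, `"sliced"`, `"kl"`, `"gamma"`.
#' @param gamma Robustness parameter for `"gamma"`.
#' @param n_projections Projections for `"sliced"`.
#' @return A function `(x, y) -> scalar`.
#' @export
make_distance <- function(name = c("wasserstein", "sliced", "kl", "gamma"),
                          gamma = 0.5, n_projections = 50) {
  name <- match.arg(name)
  switch(name,
    wasserstein = wasserstein_distance,
    sliced = function(x, y) sliced_wasserstein_distance(x, y, n_projections),
    kl = kl_divergence_knn,
    gamma = function(x, y) gamma_divergence(x, y, gamma)
  )
}
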