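#' Saltelli cross-sampling design
#'
#' Generates the radial/cross design for Sobol index estimation: two
#' independent uniform base matrices `A` and `B` of `n_base` rows plus the
#' mixed blocks `AB_i` (`A` with column i replaced from `B`) and `BA_i`,
#' for `K = n_base * (2 d + 2)` rows in total, all inside the bounds.
#'
#' Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param bounds A tibble with columns `name`, `lower`, `upper` (e.g. a
#'   [prior_uniform()] object).
#' @param n_base Base sample size `N` (powers of two recommended).
#' @return A `K x d` matrix with attributes `n_base`, `d` and `block`
#'   (block labels `"A"`, `"B"`, `"AB1"`, ..., `"BAd"`).
#' @examples
#' dim(saltelli_sample(prior_uniform(c(0, 0, 0), c(1, 1, 1)), 4))  # 32 x 3
#' @export
saltelli_sample <- function(bounds, n_base) {
  stopifnot(n_base >= 1)
  d <- nrow(bounds)
  scale_rows <- function(u) {
    u <- sweep(u, 2, bounds$upper - bounds$lower, "*")
    sweep(u, 2, bounds$lower, "+")
  }
  A <- scale_rows(matrix(runif(n_base * d), n_base, d))
  B <- scale_rows(matrix(runif(n_base * d), n_base, d))
  blocks <- list(A, B)
  labels <- c(rep("A", n_base), rep("B", n_base))
  for (i in seq_len(d)) {
    AB <- A; AB[, i] <- B[, i]
    blocks <- c(blocks, list(AB))
    labels <- c(labels, rep(paste0("AB", i), n_base))
  }
  for (i in seq_len(d)) {
    BA <- B; BA[, i] <- A[, i]
    blocks <- c(blocks, list(BA))
    labels <- c(labels, rep(paste0("BA", i), n_base))
  }
  out <- do.call(rbind, blocks)
  colnames(out) <- bounds$name
  attr(out, "n_base") <- as.integer(n_base)
  attr(out, "d") <- as.integer(d)
  attr(out, "block") <- labels
  out
}

#' Expected QoIs over a parameter design
#'
#' Evaluates the stochastic model `m_replicates` times per design row and
#' returns the per-row mean QoI vector. Simulator failures (e.g. a tree
#' exceeding its node cap) are recorded per row as `NA`.
#'
#' @param simulator Function `(theta, m, seed) -> QoI matrix` (or `NULL`),
#'   e.g. from [growth_simulator()].
#' @param X Parameter design matrix (rows = parameter points).
#' @param m_replicates Replicates per point.
#' @param seed Root seed; per-row child seeds are derived
#'   deterministically.
#' @return A tibble of per-row mean QoIs (one row per design row), with a
#'   logical attribute `failed` flagging failed rows.
#' @export
expected_qois <- function(simulator, X, m_replicates = 20, seed = 1) {
  X <- rbind(X)
  k <- nrow(X)
  failed <- logical(k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    y <- tryCatch(simulator(X[i, ], m_replicates, seed * 1e4 + i),
                  error = function(e) NULL)
    if (is.null(y)) {
      failed[i] <- TRUE
      rows[[i]] <- rep(NA_real_, 4)
    } else {
      rows[[i]] <- colMeans(as_qoi_matrix(y))
    }
  }
  m <- do.call(rbind, rows)
  if (is.null(colnames(m)))
    colnames(m) <- if (ncol(m) == 4) qoi_names() else
      paste0("y", seq_len(ncol(m)))
  out <- as_tibble(m)
  attr(out, "failed") <- failed
  out
}

#' Sobol sensitivity indices from Saltelli block outputs
#'
#' First-order indices via the Saltelli (2010) estimator and total-effect
#' indices via the Jansen estimator, averaged over the AB and BA mixed
#' blocks; 95% confidence intervals by bootstrap over the base sample
#' index. The bootstrap does not account for the inner Monte Carlo error
#' of the expected QoIs. Outputs with zero variance yield zero indices
#' with `zero_variance = TRUE`.
#'
#' @param Y Output matrix (or vector) with `K = n_base (2 d + 2)` rows
#'   aligned with [saltelli_sample()] block order, e.g. from
#'   [expected_qois()].
#' @param n_base,d Design dimensions (taken from attributes of `design`
#'   if supplied).
#' @param design Optional design matrix from [saltelli_sample()].
#' @param n_bootstrap Bootstrap replicates for the confidence intervals.
#' @param conf Confidence level.
#' @return A tibble of class `"sobol_result"`: one row per
#'   (parameter, output) with `s1`, `s1_ci`, `s_tot`, `s_tot_ci`,
#'   `zero_variance`.
#' @export
sobol_indices <- function(Y, n_base = NULL, d = NULL, design = NULL,
                          n_bootstrap = 200, conf = 0.95) {
  if (!is.null(design)) {
    n_base <- attr(design, "n_base")
    d <- attr(design, "d")
  }
  stopifnot(!is.null(n_base), !is.null(d))
  Ym <- as_qoi_matrix(Y)
  if (is.null(colnames(Ym))) colnames(Ym) <- paste0("y", seq_len(ncol(Ym)))
  if (nrow(Ym) != n_base * (2 * d + 2))
    abort("output rows do not match the Saltelli design size")
  pnames <- if (!is.null(design)) colnames(design) else paste0("x", seq_len(d))

  idx_block <- function(b) ((b - 1) * n_base + 1):(b * n_base)
  z <- stats::qnorm(1 - (1 - conf) / 2)

  res <- list()
  for (q in seq_len(ncol(Ym))) {
    y <- Ym[, q]
    fa <- y[idx_block(1)]
    fb <- y[idx_block(2)]
    fab <- lapply(seq_len(d), function(i) y[idx_block(2 + i)])
    fba <- lapply(seq_len(d), function(i) y[idx_block(2 + d + i)])
    est <- function(sel) {
      a <- fa[sel]; b <- fb[sel]
      v <- var(c(a, b))
      if (!is.finite(v) || v == 0) return(list(s1 = rep(0, d), st = rep(0, d), zero = TRUE))
      s1 <- st <- numeric(d)
      for (i in seq_len(d)) {
        abi <- fab[[i]][sel]; bai <- fba[[i]][sel]
        s1[i] <- (mean(b * (abi - a)) + mean(a * (bai - b))) / (2 * v)
        st[i] <- (mean((a - abi)^2) + mean((b - bai)^2)) / (2 * 2 * v)
      }
      list(s1 = s1, st = st, zero = FALSE)
    }
    full <- est(seq_len(n_base))
    if (full$zero) {
      res[[q]] <- tibble(parameter = pnames, output = colnames(Ym)[q],
                         s1 = 0, s1_ci = 0, s_tot = 0, s_tot_ci = 0,
                         zero_variance = TRUE)
      next
    }
    boots1 <- matrix(NA_real_, n_bootstrap, d)
    bootst <- matrix(NA_real_, n_bootstrap, d)
    for (bidx in seq_len(n_bootstrap)) {
      sel <- sample.int(n_base, n_base, replace = TRUE)
      e <- est(sel)
      if (!e$zero) {
        boots1[bidx, ] <- e$s1
        bootst[bidx, ] <- e$st
      }
    }
    res[[q]] <- tibble(
      parameter = pnames, output = colnames(Ym)[q],
      s1 = full$s1, s1_ci = z * apply(boots1, 2, sd, na.rm = TRUE),
      s_tot = full$st, s_tot_ci = z * apply(bootst, 2, sd, na.rm = TRUE),
      zero_variance = FALSE
    )
  }
  structure(dplyr::bind_rows(res),
            class = c("sobol_result", class(tibble())))
}

#' Run a full Sobol sensitivity analysis
#'
#' Convenience wrapper chaining [saltelli_sample()], [expected_qois()] and
#' [sobol_indices()].
#'
#' @param simulator As in [expected_qois()].
#' @param bounds Parameter box (see [prior_uniform()]).
#' @param n_base Base sample size.
#' @param m_replicates Replicates per design row.
#' @param n_bootstrap Bootstrap replicates.
#' @param seed Root seed (controls both design and simulations).
#' @return A `"sobol_result"` tibble (see [sobol_indices()]).
#' @export
run_sobol <- function(simulator, bounds, n_base = 256, m_replicates = 5,
                      n_bootstrap = 200, seed = 1) {
  set.seed(seed)
  X <- saltelli_sample(bounds, n_base)
  Y <- expected_qois(simulator, X, m_replicates, seed = seed)
  sobol_indices(Y, design = X, n_bootstrap = n_bootstrap)
}
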