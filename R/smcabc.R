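#' Uniform box prior
#'
#' @param lower,upper Numeric vectors of per-parameter bounds.
#' @param names Parameter names.
#' @return A tibble of class `"abc_prior"`.
#' @examples
#' prior_uniform(c(0.01, 2e-4, 20), c(0.1, 2e-3, 150), c("p_bra", "R", "v"))
#' @export
prior_uniform <- function(lower, upper, names = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (is.null(names)) names <- paste0("theta", seq_along(lower))
  structure(tibble(name = names, lower = as.numeric(lower),
                   upper = as.numeric(upper)),
            class = c("abc_prior", class(tibble())))
}

sample_prior <- function(prior, n) {
  d <- nrow(prior)
  m <- matrix(runif(n * d), n, d)
  m <- sweep(m, 2, prior$upper - prior$lower, "*")
  m <- sweep(m, 2, prior$lower, "+")
  colnames(m) <- prior$name
  m
}

prior_contains <- function(prior, theta) {
  all(theta >= prior$lower & theta <= prior$upper)
}

#' Effective sample size of a weighted ensemble
#'
#' `ESS = (sum w)^2 / sum w^2`.
#'
#' @param weights Non-negative weights, not all zero.
#' @return Scalar in `[1, length(weights)]` (0-weight particles allowed).
#' @examples
#' ess(rep(1, 8))       # 8
#' ess(c(1, 0, 0, 0))   # 1
#' @export
ess <- function(weights) {
  if (any(weights < 0)) abort("weights must be non-negative")
  s <- sum(weights)
  if (s == 0) abort("all weights are zero", class = "abcgrow_degenerate")
  s^2 / sum(weights^2)
}

#' Adapt the ABC tolerance by the ESS-fraction rule
#'
#' Finds (by bisection) the largest `eps <= eps_prev` such that the
#' effective sample size of the re-weighted system -- weights multiplied
#' by the indicator `distance < eps` -- equals `alpha` times the current
#' ESS. Because the indicator makes the ESS a step function of `eps`, the
#' bisection converges to the jump location where the ESS crosses the
#' target.
#'
#' @param distances Current particle distances.
#' @param weights Current (unnormalised) weights.
#' @param alpha Target ESS fraction in (0, 1).
#' @param eps_prev Previous tolerance (may be `Inf`).
#' @return New tolerance, `<= eps_prev`.
#' @export
adapt_epsilon <- function(distances, weights, alpha, eps_prev = Inf) {
  stopifnot(alpha > 0, alpha < 1, length(distances) == length(weights))
  finite <- is.finite(distances) & weights > 0
  if (!any(finite))
    abort("no particle with finite distance and positive weight",
          class = "abcgrow_degenerate")
  target <- alpha * ess(weights)
  ess_at <- function(e) {
    w <- weights * (distances < e)
    s <- sum(w)
    if (s == 0) 0 else s^2 / sum(w^2)
  }
  hi <- min(eps_prev, max(distances[finite]) * (1 + 1e-9))
  if (ess_at(hi) <= target) return(hi)
  lo <- 0
  tol <- 1e-8 * (if (is.finite(eps_prev)) eps_prev else hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ess_at(mid) > target) hi <- mid else lo <- mid
  }
  hi
}

#' Systematic resampling
#'
#' Draws `length(weights)` particle indices with a single uniform offset
#' over a stratified grid, guaranteeing per-particle counts within one of
#' their expectation.
#'
#' @param weights Normalised or unnormalised weights.
#' @param u Optional uniform offset in `[0, 1)` (drawn from R's RNG if
#'   `NULL`).
#' @return Integer vector of resampled indices.
#' @export
resample_systematic <- function(weights, u = NULL) {
  n <- length(weights)
  w <- weights / sum(weights)
  if (is.null(u)) u <- runif(1)
  pts <- (seq_len(n) - 1 + u) / n
  findInterval(pts, cumsum(w), left.open = TRUE) + 1L
}

#' One 2-hit MCMC move of a particle
#'
#' Proposes `theta' ~ N(theta, proposal_cov)`; proposals outside the prior
#' support are rejected without simulating. Otherwise datasets are
#' simulated for the proposal until it scores two hits (r = 2)
#' (`distance < eps`), taking `N'` datasets, and for the current particle
#' until it scores 1 hit (its stored dataset already being a hit), taking
#' `N` datasets; the proposal is accepted with probability
#' `N / (N' + N - 1)` times the prior ratio (1 for the uniform box prior).
#' This acceptance rule is in detailed balance with the ABC target at
#' level `eps` (see the methods vignette) and reduces to acceptance
#' probability 1/2 when `eps = Inf`. Internally the current particle's
#' race runs first and the acceptance uniform is drawn up front, which
#' lets the proposal race terminate exactly when acceptance has become
#' impossible -- an exact shortcut that leaves the kernel unchanged while
#' sparing simulations on hopeless proposals.
#'
#' A move that would exceed `move_cap` simulated datasets counts as a
#' rejection. A simulator returning `NULL` ("no dataset") counts as a
#' miss.
#'
#' @param particle List with elements `theta`, `distance`, `qois`.
#' @param eps Current tolerance (may be `Inf`).
#' @param prior An [prior_uniform()] object.
#' @param proposal_cov Positive-definite proposal covariance.
#' @param simulator Function `(theta, m, seed) -> QoI matrix` (or `NULL`).
#' @param distance_fn Function `(y_obs, y_sim) -> scalar` (already bound
#'   to the observed data's standardisation, if any).
#' @param y_obs Observed QoI matrix passed to `distance_fn`.
#' @param m_prime Dataset cardinality.
#' @param seed Base seed for this move's datasets.
#' @param move_cap Maximum simulated datasets per move.
#' @return List `(particle, n_sims, accepted)`; `n_sims` counts simulated
#'   datasets.
#' @export
rhit_move <- function(particle, eps, prior, proposal_cov, simulator,
                      distance_fn, y_obs, m_prime, seed,
                      move_cap = 10000) {
  theta <- particle$theta
  d <- length(theta)
  chol_cov <- tryCatch(chol(proposal_cov), error = function(e) NULL)
  if (is.null(chol_cov))
    chol_cov <- chol(proposal_cov + diag(1e-12 + 1e-8 * mean(diag(proposal_cov)),
                                         d))
  prop <- as.numeric(theta + drop(rnorm(d) %*% chol_cov))
  if (!prior_contains(prior, prop))
    return(list(particle = particle, n_sims = 0L, accepted = FALSE))

  sims_used <- 0L
  draw <- function(th) {
    sims_used <<- sims_used + 1L
    y <- simulator(th, m_prime, seed + sims_used)
    if (is.null(y)) return(list(dist = Inf, qois = NULL))
    dd <- distance_fn(y_obs, y)
    list(dist = dd, qois = y)
  }

  # The acceptance probability is N / (N' + N - 1) with N' the proposal's
  # draws to 2 hits and N the current particle's draws to 1 hit. Sampling
  # the acceptance uniform u first allows an exact early termination: the
  # move can only be accepted while N' < N / u - N + 1, so the proposal
  # race stops at that bound (the simulated-datasets law is unchanged;
  # stopping early only occurs on paths that would be rejected anyway).

  # current particle races to 1 hit; the hit dataset is a fresh draw from
  # y | theta conditioned on the hit, i.e. an exact Gibbs refresh of the
  # particle's stored dataset -- kept even when the proposal is rejected,
  # so datasets that were atypically lucky for their parameter do not
  # persist. A particle that cannot re-hit within the cap is returned
  # stale (distance Inf) and dies at the next re-weighting.
  n_cur <- 0L
  cur_hit <- NULL
  repeat {
    if (sims_used >= move_cap) {
      stale <- list(theta = theta, distance = Inf, qois = particle$qois)
      return(list(particle = stale, n_sims = sims_used, accepted = FALSE))
    }
    s <- draw(theta)
    n_cur <- n_cur + 1L
    if (s$dist < eps) {
      cur_hit <- s
      break
    }
  }
  refreshed <- list(theta = theta, distance = cur_hit$dist,
                    qois = cur_hit$qois)
  u <- runif(1)
  bound <- n_cur / u - n_cur + 1  # accept iff n_prop < bound

  hits <- 0L
  last <- NULL
  n_prop <- 0L
  while (hits < 2L) {
    if (sims_used >= move_cap || n_prop + 1 >= bound)
      return(list(particle = refreshed, n_sims = sims_used, accepted = FALSE))
    s <- draw(prop)
    n_prop <- n_prop + 1L
    if (s$dist < eps) {
      hits <- hits + 1L
      last <- s
    }
  }
  if (n_prop < bound) {
    list(particle = list(theta = prop, distance = last$dist,
                         qois = last$qois),
         n_sims = sims_used, accepted = TRUE)
  } else {
    list(particle = refreshed, n_sims = sims_used, accepted = FALSE)
  }
}

#' SMC-ABC configuration
#'
#' @param n_particles Number of particles `N`.
#' @param alpha ESS fraction controlling the tolerance schedule.
#' @param m_prime Simulated dataset cardinality `M'`.
#' @param sim_budget Total budget of single model evaluations (neurons);
#'   each dataset costs `m_prime`. The iteration during which the budget
#'   is crossed is finished before stopping.
#' @param epsilon_target Stop once the tolerance reaches this value.
#' @param resample_threshold Resample when `ESS < threshold * N`.
#' @param move_cap Maximum simulated datasets per particle move.
#' @param standardize Standardise QoIs by the observed data's per-column
#'   center/scale before computing distances.
#' @param r_hits Hit count of the move kernel (fixed at 2).
#' @param seed Root seed.
#' @param keep_history Keep per-iteration particle snapshots.
#' @return A list of class `"smc_config"`.
#' @export
smc_config <- function(n_particles = 256, alpha = 0.6, m_prime = 25,
                       sim_budget = 5e5, epsilon_target = 0,
                       resample_threshold = 0.5, move_cap = 30,
                       standardize = TRUE, r_hits = 2, seed = 1,
                       keep_history = TRUE) {
  stopifnot(n_particles >= 2, alpha > 0, alpha < 1, m_prime >= 1,
            r_hits == 2)
  structure(list(n_particles = as.integer(n_particles), alpha = alpha,
                 m_prime = as.integer(m_prime), sim_budget = sim_budget,
                 epsilon_target = epsilon_target,
                 resample_threshold = resample_threshold,
                 move_cap = move_cap, standardize = standardize,
                 r_hits = 2L, seed = as.integer(seed),
                 keep_history = keep_history),
            class = "smc_config")
}

#' Sequential Monte Carlo ABC with adaptive tolerance
#'
#' Del Moral-style SMC-ABC: `N` particles are initialised from the prior
#' (tolerance `eps_0 = Inf`) with one simulated dataset each; every
#' iteration adapts the tolerance so the ESS drops to a fraction `alpha`
#' of its current value, re-weights by the indicator `distance < eps`,
#' resamples systematically when the ESS falls below
#' `resample_threshold * N`, and moves every particle with the 2-hit MCMC
#' kernel ([rhit_move()]). The loop ends when the simulation budget is
#' exhausted (finishing the crossing iteration) or the tolerance reaches
#' `epsilon_target`.
#'
#' @param y_obs_qois Observed QoI tibble/matrix (one row per neuron).
#' @param simulator Function `(theta, m, seed) -> QoI matrix`, e.g. from
#'   [growth_simulator()].
#' @param prior An [prior_uniform()] object.
#' @param config An [smc_config()] object.
#' @param distance_fn Distance between QoI clouds (see [make_distance()]).
#' @param verbose Print one line per iteration.
#' @return An object of class `"abc_fit"`: a list with `particles` (tibble
#'   of parameter columns, `weight`, `distance`), `trace` (per-iteration
#'   tibble), `history` (particle snapshots), `prior`, `config`, and
#'   `standardization`.
#' @export
run_smcabc <- function(y_obs_qois, simulator, prior, config = smc_config(),
                       distance_fn = wasserstein_distance, verbose = FALSE) {
  stopifnot(inherits(config, "smc_config"))
  set.seed(config$seed)
  n <- config$n_particles
  mp <- config$m_prime
  y_obs <- as_qoi_matrix(y_obs_qois)

  stats <- NULL
  if (config$standardize) {
    stats <- qoi_standardization(y_obs)
    y_obs_d <- as_qoi_matrix(standardize(y_obs, stats))
    dist_fn <- function(a, b) distance_fn(a, as_qoi_matrix(standardize(b, stats)))
  } else {
    y_obs_d <- y_obs
    dist_fn <- function(a, b) distance_fn(a, as_qoi_matrix(b))
  }

  theta <- sample_prior(prior, n)
  qois <- vector("list", n)
  dists <- numeric(n)
  init_seeds <- sample.int(.Machine$integer.max - 1, n)
  for (i in seq_len(n)) {
    y <- simulator(theta[i, ], mp, init_seeds[i])
    if (is.null(y)) {
      dists[i] <- Inf
    } else {
      qois[[i]] <- y
      dists[i] <- dist_fn(y_obs_d, y)
    }
  }
  w <- rep(1 / n, n)
  cum_sims <- n * mp
  eps <- Inf
  it <- 0L
  trace <- list()
  history <- list()

  while (cum_sims < config$sim_budget) {
    it <- it + 1L
    eps_new <- tryCatch(
      adapt_epsilon(dists, w, config$alpha, eps),
      abcgrow_degenerate = function(e) {
        abort("degenerate particle population",
              class = "abcgrow_degenerate",
              trace_data = dplyr::bind_rows(trace))
      }
    )
    eps <- eps_new
    w <- w * (dists < eps)
    if (sum(w) == 0)
      abort("degenerate particle population",
            class = "abcgrow_degenerate", trace_data = dplyr::bind_rows(trace))
    w <- w / sum(w)
    if (ess(w) < config$resample_threshold * n) {
      idx <- resample_systematic(w)
      theta <- theta[idx, , drop = FALSE]
      qois <- qois[idx]
      dists <- dists[idx]
      w <- rep(1 / n, n)
    }
    pcov <- 2 * cov.wt(theta, wt = w)$cov
    if (any(!is.finite(pcov))) pcov <- diag(1e-12, ncol(theta))
    move_seeds <- sample.int(.Machine$integer.max - 1, n)
    acc <- 0L
    for (i in seq_len(n)) {
      if (w[i] == 0) next
      res <- rhit_move(
        list(theta = theta[i, ], distance = dists[i], qois = qois[[i]]),
        eps, prior, pcov, simulator, dist_fn, y_obs_d, mp,
        seed = move_seeds[i], move_cap = config$move_cap
      )
      cum_sims <- cum_sims + res$n_sims * mp
      if (res$accepted) acc <- acc + 1L
      # rejected moves may still carry a refreshed (or stale) dataset
      theta[i, ] <- res$particle$theta
      dists[i] <- res$particle$distance
      qois[[i]] <- res$particle$qois
    }
    trace[[it]] <- tibble(
      iteration = it, epsilon = eps, ess = ess(w),
      acceptance_rate = acc / n, cum_sims = cum_sims
    )
    if (config$keep_history) {
      snap <- as_tibble(theta)
      snap$weight <- w
      snap$iteration <- it
      history[[it]] <- snap
    }
    if (verbose)
      message(sprintf("iter %3d  eps %.4g  ESS %.1f  acc %.2f  sims %.3g",
                      it, eps, ess(w), acc / n, cum_sims))
    if (eps <= config$epsilon_target) break
  }

  particles <- as_tibble(theta)
  particles$weight <- w / sum(w)
  particles$distance <- dists
  structure(
    list(particles = particles, trace = dplyr::bind_rows(trace),
         history = history, prior = prior, config = config,
         standardization = stats, n_iterations = it, cum_sims = cum_sims),
    class = "abc_fit"
  )
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf(
    "<abc_fit> %d particles, %d iterations, final eps %.4g, ESS %.1f, %.3g simulations\n",
    nrow(x$particles), x$n_iterations,
    if (nrow(x$trace)) x$trace$epsilon[nrow(x$trace)] else Inf,
    ess(x$particles$weight), x$cum_sims
  ))
  invisible(x)
}
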