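test_that("effective sample size identities", {
  expect_equal(ess(rep(1 / 8, 8)), 8)
  expect_equal(ess(c(1, 0, 0, 0)), 1)
  expect_equal(ess(c(0.5, 0.5, 0, 0)), 2)
  expect_equal(ess(rep(3, 10)), 10)  # scale invariant
  expect_error(ess(c(0, 0)), class = "abcgrow_degenerate")
})

test_that("tolerance adaptation matches a grid-search oracle", {
  grid_oracle <- function(d, w, alpha) {
    target <- alpha * ess(w)
    cand <- sort(unique(d[is.finite(d)]))
    ess_at <- function(e) {
      ww <- w * (d < e)
      if (sum(ww) == 0) 0 else sum(ww)^2 / sum(ww^2)
    }
    # smallest candidate (open on the left) whose ESS exceeds the target
    for (e in cand) {
      if (ess_at(e * (1 + 1e-12) + 1e-300) > target) return(e)
    }
    max(cand)
  }
  set.seed(13)
  for (r in 1:25) {
    n <- sample(5:60, 1)
    d <- rexp(n, 0.2)
    w <- runif(n)
    alpha <- runif(1, 0.2, 0.9)
    got <- adapt_epsilon(d, w, alpha, Inf)
    want <- grid_oracle(d, w, alpha)
    expect_equal(got, want, tolerance = 1e-6)
    expect_lte(got, max(d) * (1 + 1e-6))
    # monotonicity: never exceeds the previous tolerance
    prev <- want * runif(1, 0.9, 2)
    expect_lte(adapt_epsilon(d, w, alpha, prev), prev)
  }
  # two-particle example: distances (1, 3), alpha = 0.4 -> ESS 1 at the jump
  e <- adapt_epsilon(c(1, 3), c(0.5, 0.5), 0.4, Inf)
  expect_gt(e, 1 - 1e-6)
  expect_lte(e, 3)
  w_new <- c(0.5, 0.5) * (c(1, 3) < e + 1e-9)
  expect_equal(sum(w_new)^2 / sum(w_new^2), 1)
})

test_that("systematic resampling preserves the ensemble in expectation", {
  # uniform weights: every particle copied exactly once
  expect_equal(sort(resample_systematic(rep(1, 10), u = 0.3)), 1:10)
  # one-hot weights: n copies of that particle
  expect_equal(resample_systematic(c(0, 1, 0), u = 0.5), rep(2L, 3))
  # weighted mean of theta preserved over a thousand resamplings
  set.seed(14)
  theta <- rnorm(20)
  w <- runif(20); w <- w / sum(w)
  means <- vapply(seq_len(1000), function(i)
    mean(theta[resample_systematic(w)]), numeric(1))
  target <- sum(w * theta)
  expect_lt(abs(mean(means) - target), 3 * sd(means) / sqrt(1000) + 1e-9)
  # counts within one of the expectation
  cnt <- tabulate(resample_systematic(w), 20)
  expect_true(all(abs(cnt - 20 * w) <= 1))
})

test_that("out-of-prior proposals are rejected without simulating", {
  prior <- prior_uniform(0, 1, "th")
  particle <- list(theta = c(th = 0.5), distance = 0.1,
                   qois = matrix(0.5))
  boom <- function(theta, m, seed) stop("must not simulate")
  # sd = 100 proposals land outside [0, 1] with probability ~0.996
  set.seed(1)
  out <- rhit_move(particle, eps = 1, prior, proposal_cov = diag(1e4, 1),
                   simulator = boom, distance_fn = function(a, b) 0,
                   y_obs = matrix(0), m_prime = 1, seed = 1)
  expect_false(out$accepted)
  expect_equal(out$n_sims, 0L)
})

test_that("with eps = Inf the kernel accepts half the proposals and targets the prior", {
  # every dataset is a hit: N' = 2, N = 1, acceptance N/(N'+N-1) = 1/2;
  # the chain then reduces to a random-walk sampler of the uniform prior
  prior <- prior_uniform(0, 1, "th")
  sim <- function(theta, m, seed) matrix(0)
  dist_fn <- function(a, b) 0
  set.seed(15)
  th <- 0.5
  n_moves <- 8000
  acc <- 0
  samples <- numeric(n_moves)
  for (i in seq_len(n_moves)) {
    out <- rhit_move(list(theta = th, distance = 0, qois = matrix(0)),
                     eps = Inf, prior, diag(0.04, 1), sim, dist_fn,
                     matrix(0), 1, seed = i)
    # 0 (support rejection), 2 (early-terminated race) or 3 (full race)
    expect_equal(out$n_sims %in% c(0L, 2L, 3L), TRUE)
    if (out$accepted) acc <- acc + 1
    th <- out$particle$theta
    samples[i] <- th
  }
  # in-support proposals are accepted with probability exactly 1/2; the
  # overall rate is lower because proposals may leave the prior box
  expect_gt(acc / n_moves, 0.25)
  expect_lt(acc / n_moves, 0.5)
  ks <- suppressWarnings(stats::ks.test(samples[seq(2000, n_moves, 3)],
                                        "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the 2-hit kernel leaves a tractable ABC target invariant", {
  # model y ~ N(theta, 1), dataset = one draw, hit iff |y - y0| < eps;
  # ABC posterior on uniform [-3, 3] is prop. to
  # Phi(y0 + eps - theta) - Phi(y0 - eps - theta)
  y0 <- 0.3
  eps <- 0.5
  dens <- function(th) pnorm(y0 + eps - th) - pnorm(y0 - eps - th)
  rexact <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- runif(3 * n, -3, 3)
      keep <- runif(3 * n) < dens(cand) / dens(y0)
      out <- c(out, cand[keep])
    }
    out[seq_len(n)]
  }
  prior <- prior_uniform(-3, 3, "th")
  sim <- function(theta, m, seed) matrix(rnorm(1, theta[1], 1))
  dist_fn <- function(a, b) abs(a[1, 1] - b[1, 1])
  set.seed(16)
  n_part <- 2000
  th <- rexact(n_part)
  for (sweep_i in 1:50) {
    for (j in seq_len(n_part)) {
      out <- rhit_move(list(theta = th[j], distance = 0, qois = matrix(y0)),
                       eps = eps, prior, diag(0.5, 1), sim, dist_fn,
                       matrix(y0), 1, seed = sweep_i * n_part + j,
                       move_cap = 1000)
      if (out$accepted) th[j] <- out$particle$theta
    }
  }
  ks <- suppressWarnings(stats::ks.test(th, rexact(n_part)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a budget of exactly N * M' yields an iid prior sample", {
  prior <- prior_uniform(c(-1, 10), c(1, 20), c("a", "b"))
  cfg <- smc_config(n_particles = 200, m_prime = 5, sim_budget = 1000,
                    standardize = FALSE, seed = 3)
  fit <- run_smcabc(matrix(rnorm(50), 50, 1),
                    function(theta, m, seed) matrix(rnorm(m), m, 1),
                    prior, cfg)
  expect_equal(fit$n_iterations, 0L)
  expect_equal(fit$particles$weight, rep(1 / 200, 200))
  ks <- suppressWarnings(stats::ks.test(fit$particles$a, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("the sampler recovers the conjugate Gaussian posterior", {
  set.seed(99)
  y_obs <- matrix(rnorm(100, 1, 1), ncol = 1)
  prior <- prior_uniform(-3, 5, "mu")
  cfg <- smc_config(n_particles = 512, m_prime = 100, sim_budget = 4e6,
                    standardize = FALSE, seed = 7, move_cap = 30)
  fit <- run_smcabc(y_obs, gaussian_toy_simulator, prior, cfg)
  td <- tidy(fit)
  post_mean <- mean(y_obs)       # flat-prior posterior: N(ybar, 1/n)
  post_sd <- 1 / sqrt(100)
  n_eff <- ess(fit$particles$weight)
  expect_lt(abs(td$mean - post_mean), 3 * post_sd / sqrt(n_eff) + 0.01)
  expect_lt(abs(td$sd - post_sd), 3 * post_sd / sqrt(2 * n_eff) + 0.01)
  # trace invariants: eps non-increasing, weights normalised, budget honoured
  expect_true(all(diff(fit$trace$epsilon) <= 1e-12))
  expect_equal(sum(fit$particles$weight), 1)
  expect_lt(fit$cum_sims, cfg$sim_budget + 512 * 30 * 100)
})

test_that("full runs are deterministic given the seed", {
  y_obs <- matrix(rnorm(40, 1, 1), ncol = 1)
  prior <- prior_uniform(-2, 4, "mu")
  cfg <- smc_config(n_particles = 64, m_prime = 20, sim_budget = 4e4,
                    standardize = FALSE, seed = 5, move_cap = 20)
  f1 <- run_smcabc(y_obs, gaussian_toy_simulator, prior, cfg)
  f2 <- run_smcabc(y_obs, gaussian_toy_simulator, prior, cfg)
  expect_identical(as.data.frame(f1$particles), as.data.frame(f2$particles))
  expect_identical(as.data.frame(f1$trace), as.data.frame(f2$trace))
})
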