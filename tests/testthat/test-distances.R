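test_that("standardisation gives unit-variance columns and detects degeneracy", {
  set.seed(3)
  x <- matrix(rnorm(200, c(10, 100), c(2, 30)), 100, 2, byrow = TRUE)
  colnames(x) <- c("a", "b")
  st <- qoi_standardization(x)
  z <- abcgrow:::as_qoi_matrix(standardize(x, st))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_equal(unname(colMeans(z)), c(0, 0))
  # identity stats leave data unchanged
  id <- st; id$center <- 0; id$scale <- 1
  expect_equal(abcgrow:::as_qoi_matrix(standardize(x, id)), x,
               ignore_attr = TRUE)
  # affine consistency: standardising a*x+b with matching stats equals z
  y <- sweep(sweep(x, 2, c(2, 0.5), "*"), 2, c(1, -3), "+")
  sty <- qoi_standardization(y)
  expect_equal(abcgrow:::as_qoi_matrix(standardize(y, sty)), z,
               ignore_attr = TRUE, tolerance = 1e-12)
  # zero-variance column errors
  x[, 2] <- 7
  expect_error(qoi_standardization(x), class = "abcgrow_zero_scale")
})

test_that("Wasserstein distance is an exact metric on point clouds", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(wasserstein_distance(x, x), 0)
  # 1-D clouds {0,1} vs {1,2}: sorted matching gives 1
  expect_equal(wasserstein_distance(matrix(c(0, 1)), matrix(c(1, 2))), 1)
  # symmetry, non-negativity, triangle inequality on random triples
  for (r in 1:20) {
    a <- matrix(rnorm(24), 8); b <- matrix(rnorm(24), 8)
    cc <- matrix(rnorm(24), 8)
    dab <- wasserstein_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, wasserstein_distance(b, a))
    expect_lte(dab, wasserstein_distance(a, cc) +
                 wasserstein_distance(cc, b) + 1e-10)
  }
  # translation equivariance: shifting one cloud by t moves W2 to ||t||
  t_vec <- c(3, -4, 0)
  expect_equal(wasserstein_distance(x, sweep(x, 2, t_vec, "+")),
               sqrt(sum(t_vec^2)))
  # permutation invariance over rows
  y <- matrix(rnorm(60), 20, 3)
  expect_equal(wasserstein_distance(x, y),
               wasserstein_distance(x[sample(20), ], y[sample(20), ]))
})

test_that("Wasserstein solver agrees with an independent assignment oracle", {
  skip_if_not_installed("clue")
  set.seed(5)
  for (r in 1:10) {
    n <- 40; m <- sample(c(8, 20, 40), 1); d <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n); y <- matrix(rnorm(m * d), m)
    yy <- y[rep(seq_len(m), each = n / m), , drop = FALSE]
    cost <- outer(seq_len(n), seq_len(n),
                  Vectorize(function(i, j) sum((x[i, ] - yy[j, ])^2)))
    oracle <- sqrt(mean(cost[cbind(seq_len(n), clue::solve_LSAP(cost))]))
    expect_equal(wasserstein_distance(x, y), oracle, tolerance = 1e-10)
  }
})

test_that("Gaussian mean shift reproduces the closed-form Wasserstein value", {
  # equal-covariance Gaussians: W2 = ||mu1 - mu2|| = sqrt(d)
  set.seed(6)
  for (d in c(1, 4)) {
    C <- 0.8 * diag(d) + 0.2
    L <- chol(C)
    x <- matrix(rnorm(1000 * d), 1000) %*% L
    y <- sweep(matrix(rnorm(1000 * d), 1000) %*% L, 2, 1, "+")
    expect_equal(wasserstein_distance(x, y), sqrt(d), tolerance = 0.1)
  }
})

test_that("sliced Wasserstein collapses to exact W in 1-D and is below it in 2-D", {
  set.seed(7)
  x <- matrix(rnorm(50)); y <- matrix(rnorm(50, 1))
  expect_equal(sliced_wasserstein_distance(x, y, 10),
               wasserstein_distance(x, y))
  expect_equal(sliced_wasserstein_distance(x, x, 5), 0)
  # projection inequality for separated 2-D Gaussians
  x2 <- matrix(rnorm(400), 200); y2 <- sweep(matrix(rnorm(400), 200), 2, 2, "+")
  set.seed(8)
  expect_lte(sliced_wasserstein_distance(x2, y2, 200),
             wasserstein_distance(x2, y2) + 0.05)
})

test_that("KL estimator matches the Gaussian closed form and scales quadratically", {
  set.seed(9)
  x <- matrix(rnorm(10000)); y <- matrix(rnorm(10000, 1))
  # KL(N(0,1) || N(1,1)) = 0.5
  expect_equal(kl_divergence_knn(x, y), 0.5, tolerance = 0.1)
  # asymmetry of generic clouds
  a <- matrix(rnorm(300), 100, 3)
  b <- matrix(rnorm(300, 0.5, 1.4), 100, 3)
  expect_false(isTRUE(all.equal(kl_divergence_knn(a, b),
                                kl_divergence_knn(b, a))))
  # quadratic scaling in the mean shift: shift 2d vs d gives ratio ~ 4
  x <- matrix(rnorm(8000)); y1 <- matrix(rnorm(8000, 0.5))
  y2 <- matrix(rnorm(8000, 1))
  ratio <- kl_divergence_knn(x, y2) / kl_divergence_knn(x, y1)
  expect_equal(ratio, 4, tolerance = 0.35)
})

test_that("gamma divergence approaches KL for small gamma and damps outliers", {
  set.seed(10)
  x <- matrix(rnorm(2000)); y <- matrix(rnorm(2000, 0.8))
  expect_equal(gamma_divergence(x, x, gamma = 0.5), 0, tolerance = 0.05)
  expect_equal(gamma_divergence(x, y, gamma = 1e-3),
               kl_divergence_knn(x, y), tolerance = 0.02)
  # 1% far outliers in the sample perturb gamma (0.5) less than the KL
  # estimate: the power mean damps outlying log-density ratios that enter
  # the KL average linearly
  x_cont <- x
  x_cont[seq_len(20)] <- 60 + rnorm(20)
  d_kl <- abs(kl_divergence_knn(x_cont, y) - kl_divergence_knn(x, y))
  d_g <- abs(gamma_divergence(x_cont, y, 0.5) - gamma_divergence(x, y, 0.5))
  expect_lt(d_g, d_kl)
})

test_that("all distances are permutation invariant", {
  set.seed(11)
  x <- matrix(rnorm(120), 40, 3); y <- matrix(rnorm(120, 0.3), 40, 3)
  px <- x[sample(40), ]; py <- y[sample(40), ]
  expect_equal(wasserstein_distance(x, y), wasserstein_distance(px, py))
  expect_equal(kl_divergence_knn(x, y), kl_divergence_knn(px, py))
  expect_equal(gamma_divergence(x, y, 0.5), gamma_divergence(px, py, 0.5))
  set.seed(1); s1 <- sliced_wasserstein_distance(x, y, 20)
  set.seed(1); s2 <- sliced_wasserstein_distance(px, py, 20)
  expect_equal(s1, s2)
})

test_that("Wasserstein estimation error shrinks with sample size", {
  # mean-shifted equal-covariance Gaussians, d = 1: truth is 1
  set.seed(12)
  med_err <- vapply(c(10, 100, 1000), function(n) {
    errs <- vapply(seq_len(100), function(r) {
      x <- matrix(rnorm(n)); y <- matrix(rnorm(n, 1))
      abs(wasserstein_distance(x, y) - 1)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})
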