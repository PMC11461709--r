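test_that("elongation direction combines persistence, gradient and noise", {
  set.seed(1)
  # persistence only: returns the orientation for any gradient
  expect_equal(elongation_direction(c(0, 0, 1), c(5, -2, 3), c(0, 1, 0)),
               c(0, 0, 1))
  # gradient only: normalised gradient
  expect_equal(elongation_direction(c(0, 0, 1), c(2, 0, 0), c(0, 0, 1)),
               c(1, 0, 0))
  # persistence + gradient: sum of two unit vectors, renormalised
  expect_equal(elongation_direction(c(1, 0, 0), c(0, 3, 0), c(0, 1, 1)),
               c(1, 1, 0) / sqrt(2))
  # random component gives a unit vector
  d <- elongation_direction(c(0, 0, 1), c(0, 0, 0), c(1, 0.5, 0))
  expect_equal(sum(d^2), 1)
  # zero resultant signals a degenerate-direction error
  expect_error(elongation_direction(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1)),
               class = "abcgrow_degenerate_direction")
})

test_that("elongation shifts the endpoint, consumes resource, splits long agents", {
  p <- model_params(model_id = 2, v = 1, R = 0.00071, l_max = 10)
  tip <- chain_tree(1)[2, ]
  out <- apply_elongation(tip, c(0, 0, 1), p)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$end_x, out$end_y, out$end_z), c(0, 0, 2))
  expect_equal(out$resource, 1 - 0.00071)  # 0.99929
  # length-12 agent with l_max 10 splits into two collinear halves
  long <- tip
  long$end_z <- long$start_z + 11
  p2 <- update_params(p, v = 1, l_max = 10)
  out2 <- apply_elongation(long, c(0, 0, 1), p2)
  expect_equal(nrow(out2), 2)
  lens <- sqrt((out2$end_z - out2$start_z)^2)
  expect_equal(lens, c(6, 6))
  expect_equal(out2$end_z[1], out2$start_z[2])  # collinear, contiguous
  expect_equal(out2$parent[2], out2$id[1])      # distal is the child tip
})

test_that("branching distributes resource by model", {
  tip <- chain_tree(1)[2, ]
  tip$resource <- 0.4
  set.seed(5)
  # Model 1: both daughters inherit the mother's resource
  d1 <- branch_tip(tip, model_params(model_id = 1))
  expect_equal(nrow(d1), 2)
  expect_equal(d1$resource, c(0.4, 0.4))
  # daughters deflected symmetrically by theta_b from the mother
  o <- c(tip$orient_x, tip$orient_y, tip$orient_z)
  cosang <- c(sum(d1[1, c("orient_x", "orient_y", "orient_z")] * o),
              sum(d1[2, c("orient_x", "orient_y", "orient_z")] * o))
  expect_equal(cosang, rep(cos(30 * pi / 180), 2))
  # Model 2: continuation inherits, side branch gets r_0
  d2 <- branch_tip(tip, model_params(model_id = 2, r_0 = 0.2))
  expect_equal(d2$resource, c(0.4, 0.2))
  expect_equal(unlist(d2[1, c("orient_x", "orient_y", "orient_z")],
                      use.names = FALSE), o)
})

test_that("idle tips and zero branching leave the tree unchanged", {
  p <- tiny_params(model_id = 1)
  tr <- chain_tree(3)
  tr$resource <- p$r_min  # not above threshold -> idle
  out <- step_model(tr, p, seed = 3)
  expect_equal(as.data.frame(out[, 1:13]), as.data.frame(tr[, 1:13]))
  # p_bra = 0: tip count constant over many steps
  p0 <- tiny_params(model_id = 1, p_bra = 0, n_steps = 40)
  n <- simulate_neuron(p0, init = init_neuron(n_apical = 0, n_basal = 3,
                                              r_init = 1), seed = 9)
  neur <- n[n$kind == "neurite", ]
  tips <- sum(!(neur$id %in% neur$parent))
  expect_equal(tips, 3)
})

test_that("branching counts follow Binomial(n k, p_bra)", {
  # k = 3 active tips held fixed by re-running single steps on the same
  # initial tree (v = 0 so no elongation splits); Monte-Carlo mean within
  # 3 standard errors
  p <- model_params(model_id = 1, p_bra = 0.05, v = 0, R = 1e-4, l_max = 20)
  tr <- init_neuron(n_apical = 0, n_basal = 3, r_init = 1)
  n_rep <- 4000
  k <- 3
  set.seed(42)
  seeds <- sample.int(1e6, n_rep)
  events <- vapply(seeds, function(s) {
    out <- step_model(tr, p, seed = s)
    sum(out$kind == "neurite") - k
  }, numeric(1)) / 2  # each branching adds two daughters
  p_hat <- mean(events) / k
  se <- sqrt(p$p_bra * (1 - p$p_bra) / (n_rep * k))
  expect_lt(abs(p_hat - p$p_bra), 3 * se)
  expect_lt(abs(var(events) - k * p$p_bra * (1 - p$p_bra)),
            3 * var(events) / sqrt(n_rep) + 0.01)
})

test_that("trees stay valid and resources never increase over steps", {
  for (mid in 1:2) {
    p <- tiny_params(model_id = mid, n_steps = 1)
    tr <- abcgrow:::default_init(p, NULL)
    res_prev <- setNames(tr$resource[tr$kind == "neurite"],
                         tr$id[tr$kind == "neurite"])
    len_prev <- sum(agent_lengths(tr))
    set.seed(mid)
    for (s in 1:25) {
      tr <- step_model(tr, p, seed = sample.int(1e6, 1))
      expect_silent(validate_neuron_tree(tr))
      neur <- tr[tr$kind == "neurite", ]
      res_now <- setNames(neur$resource, neur$id)
      common <- intersect(names(res_prev), names(res_now))
      expect_true(all(res_now[common] <= res_prev[common] + 1e-12))
      # length added per step bounded by v * active tips
      tips <- sum(!(neur$id %in% neur$parent))
      len_now <- sum(agent_lengths(tr))
      expect_lte(len_now - len_prev, p$v * tips + 1e-9)
      res_prev <- res_now
      len_prev <- len_now
    }
  }
})

test_that("simulation is a pure function of the seed", {
  p <- tiny_params(model_id = 2)
  a <- simulate_neuron(p, seed = 123)
  b <- simulate_neuron(p, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- simulate_dataset(p, m = 3, seed = 77)
  d2 <- simulate_dataset(p, m = 3, seed = 77)
  expect_identical(purrr::map(d, as.data.frame), purrr::map(d2, as.data.frame))
  # different seeds give different trees when branching is possible
  trees <- simulate_dataset(p, m = 30, seed = 5)
  keys <- vapply(trees, function(t) paste(round(t$end_x, 6), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("v = 0 freezes total length; Model 2 resources respect the decay floor", {
  p <- tiny_params(model_id = 2, v = 0)
  init <- init_neuron(n_apical = 1, r_init = 1)
  out <- simulate_neuron(p, init = init, seed = 4)
  expect_equal(sum(agent_lengths(out)), sum(agent_lengths(init)))
  p2 <- model_params(model_id = 2, n_steps = 2000)  # run past extinction
  out2 <- simulate_neuron(p2, seed = 8)
  res <- out2$resource[out2$kind == "neurite"]
  expect_true(all(res >= p2$r_min - p2$R - 1e-12))
})

test_that("dataset simulation matches per-neuron morphometrics", {
  p <- tiny_params(model_id = 2)
  q_fast <- simulate_qois(p, m = 5, seed = 31)
  trees <- simulate_dataset(p, m = 5, seed = 31)
  q_slow <- dataset_qois(trees)
  expect_equal(as.matrix(q_fast), abcgrow:::as_qoi_matrix(q_slow),
               ignore_attr = TRUE)
})

test_that("guidance field gradient is consistent with its value", {
  f <- guidance_field(c(0.5, -1, 2))
  x <- c(1, 2, 3)
  h <- 1e-6
  fd <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (f$value(x + e, 0) - f$value(x - e, 0)) / (2 * h)
  }, numeric(1))
  expect_equal(fd, drop(f$gradient(x, 0)), tolerance = 1e-6)
  # the gradient visibly biases growth along its direction
  p <- tiny_params(model_id = 2, p_bra = 0, w_rand = 0.3, w_old = 0.2,
                   w_grad = 0.5)
  up <- simulate_neuron(p, field = guidance_field(c(0, 0, 1)), seed = 2)
  down <- simulate_neuron(p, field = guidance_field(c(0, 0, -1)), seed = 2)
  expect_gt(max(up$end_z), abs(min(down$end_z)) * 0.5)
  expect_gt(max(up$end_z), 0)
})
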