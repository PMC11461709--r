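#' Elongation direction of a growing tip
#'
#' The tip executes a persistent, biased random walk: the new direction is
#' the normalised sum of a random unit vector (weight `w_rand`), the tip's
#' current orientation (weight `w_old`), and the normalised guidance-cue
#' gradient (weight `w_grad`).
#'
#' Uses R's random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param orientation Current unit orientation (length 3).
#' @param gradient Guidance-cue gradient at the tip (length 3; a zero
#'   vector contributes nothing).
#' @param weights Numeric `c(w_rand, w_old, w_grad)`.
#' @return A unit length-3 vector.
#' @examples
#' elongation_direction(c(0, 0, 1), c(0, 0, 0), c(0, 1, 0))
#' @export
elongation_direction <- function(orientation, gradient, weights) {
  stopifnot(length(orientation) == 3, length(gradient) == 3,
            length(weights) == 3, all(weights >= 0))
  u <- random_unit_vector()
  gn <- sqrt(sum(gradient^2))
  ghat <- if (gn > 0) gradient / gn else c(0, 0, 0)
  d <- weights[1] * u + weights[2] * orientation + weights[3] * ghat
  dn <- sqrt(sum(d^2))
  if (dn < 1e-12)
    abort("degenerate elongation direction (zero resultant vector)",
          class = "abcgrow_degenerate_direction")
  d / dn
}

random_unit_vector <- function() {
  repeat {
    u <- rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-12) return(u / n)
  }
}

#' Elongate a tip agent
#'
#' Shifts the tip's endpoint by `v * direction`, consumes `R` resource and,
#' if the resulting cylinder exceeds `l_max`, splits it into two collinear
#' halves (the distal half is the new tip and carries the resource).
#'
#' @param tip One-row tibble describing a tip agent (as in a `neuron_tree`).
#' @param direction Unit length-3 elongation direction.
#' @param params A [model_params()] object.
#' @return A tibble with one row (no split) or two rows (proximal, distal).
#' @export
apply_elongation <- function(tip, direction, params) {
  stopifnot(nrow(tip) == 1)
  tip$end_x <- tip$end_x + params$v * direction[1]
  tip$end_y <- tip$end_y + params$v * direction[2]
  tip$end_z <- tip$end_z + params$v * direction[3]
  tip$resource <- tip$resource - params$R
  tip$orient_x <- direction[1]
  tip$orient_y <- direction[2]
  tip$orient_z <- direction[3]
  len <- sqrt((tip$end_x - tip$start_x)^2 + (tip$end_y - tip$start_y)^2 +
                (tip$end_z - tip$start_z)^2)
  if (len <= params$l_max) return(tip)
  mid <- c((tip$start_x + tip$end_x) / 2, (tip$start_y + tip$end_y) / 2,
           (tip$start_z + tip$end_z) / 2)
  proximal <- tip
  proximal$end_x <- mid[1]; proximal$end_y <- mid[2]; proximal$end_z <- mid[3]
  distal <- tip
  distal$start_x <- mid[1]; distal$start_y <- mid[2]; distal$start_z <- mid[3]
  distal$parent <- tip$id
  distal$id <- tip$id + 1L  # caller re-assigns ids within a full tree
  dplyr::bind_rows(proximal, distal)
}

#' Branch a tip agent
#'
#' Model 1 replaces the tip by two daughters deflected symmetrically by
#' `theta_bifurcate_deg` from the mother's orientation within a random
#' plane; both inherit the mother's resource. Model 2 adds a continuation
#' daughter (inherits resource and orientation) and a side branch deflected
#' by `theta_side_deg` with resource `r_0`.
#'
#' Uses R's random number generator for the deflection plane.
#'
#' @param tip One-row tibble describing a tip agent.
#' @param params A [model_params()] object.
#' @return A tibble of two daughter rows (zero-length agents at the tip's
#'   endpoint); ids are provisional and re-assigned by the caller.
#' @export
branch_tip <- function(tip, params) {
  stopifnot(nrow(tip) == 1)
  o <- c(tip$orient_x, tip$orient_y, tip$orient_z)
  w <- random_perpendicular(o)
  daughter <- function(dir, res, id_off) {
    d <- tip
    d$id <- tip$id + id_off
    d$parent <- tip$id
    d$start_x <- tip$end_x; d$start_y <- tip$end_y; d$start_z <- tip$end_z
    d$end_x <- tip$end_x; d$end_y <- tip$end_y; d$end_z <- tip$end_z
    d$orient_x <- dir[1]; d$orient_y <- dir[2]; d$orient_z <- dir[3]
    d$resource <- res
    d
  }
  if (params$model_id == 1) {
    th <- params$theta_bifurcate_deg * pi / 180
    d1 <- cos(th) * o + sin(th) * w
    d2 <- cos(th) * o - sin(th) * w
    dplyr::bind_rows(daughter(d1, tip$resource, 1L),
                     daughter(d2, tip$resource, 2L))
  } else {
    th <- params$theta_side_deg * pi / 180
    ds <- cos(th) * o + sin(th) * w
    dplyr::bind_rows(daughter(o, tip$resource, 1L),
                     daughter(ds, params$r_0, 2L))
  }
}

random_perpendicular <- function(o) {
  repeat {
    u <- random_unit_vector()
    w <- u - sum(u * o) * o
    n <- sqrt(sum(w^2))
    if (n > 1e-9) return(w / n)
  }
}

#' Advance a neuron tree by one time step
#'
#' Every active tip (`resource > r_min`) elongates via the persistent
#' biased walk and then branches independently with probability `p_bra`;
#' in Model 2, every agent's resource additionally decays by `R` down to
#' the floor `r_min - R`. Idle agents are unchanged.
#'
#' @param tree A `neuron_tree`.
#' @param params A [model_params()] object.
#' @param field A [guidance_field()].
#' @param seed Integer seed for this step (drawn from R's RNG if `NULL`).
#' @return The advanced `neuron_tree`.
#' @export
step_model <- function(tree, params, field = guidance_field(), seed = NULL) {
  validate_neuron_tree(tree)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  p1 <- unclass(params)
  p1$n_steps <- 1L
  mat <- cpp_simulate_tree(tree_to_cpp(tree), p1,
                           field_gradient_vector(field), as.numeric(seed),
                           prune = FALSE)
  tree_from_cpp(mat, soma_row_of(tree))
}

#' Simulate one neuron
#'
#' Applies the stochastic growth rules for `params$n_steps` steps starting
#' from `init`. Fully deterministic given `seed` (the simulator uses its
#' own counter-based generator, independent of R's RNG state).
#'
#' @param params A [model_params()] object.
#' @param init Initial `neuron_tree`; default is a single apical stub for
#'   Model 2 and three basal stubs for Model 1 (see [init_neuron()]).
#' @param field A [guidance_field()].
#' @param seed Integer seed.
#' @return A `neuron_tree` tibble.
#' @examples
#' p <- model_params(model_id = 2, n_steps = 50)
#' n <- simulate_neuron(p, seed = 1)
#' compute_morphometrics(n)
#' @export
simulate_neuron <- function(params, init = NULL, field = guidance_field(),
                            seed = 1) {
  init <- default_init(params, init)
  validate_neuron_tree(init)
  mat <- cpp_simulate_tree(tree_to_cpp(init), unclass(params),
                           field_gradient_vector(field), as.numeric(seed))
  tree_from_cpp(mat, soma_row_of(init))
}

default_init <- function(params, init) {
  if (!is.null(init)) return(init)
  if (params$model_id == 2) {
    init_neuron(n_apical = 1, n_basal = 0, r_init = params$r_init)
  } else {
    init_neuron(n_apical = 0, n_basal = 3, r_init = params$r_init)
  }
}

# deterministic child-seed derivation; the C++ generator scrambles seeds,
# so consecutive integers give independent streams
child_seeds <- function(seed, m) as.numeric(seed) * 1e5 + seq_len(m)

#' Simulate a dataset of independent neurons
#'
#' @param params,init,field As in [simulate_neuron()].
#' @param m Number of neurons.
#' @param seed Root seed; per-neuron child seeds are derived
#'   deterministically, so the result is reproducible and independent of
#'   R's RNG state.
#' @return A list of `m` `neuron_tree` tibbles.
#' @export
simulate_dataset <- function(params, m, init = NULL,
                             field = guidance_field(), seed = 1) {
  stopifnot(m >= 1)
  init <- default_init(params, init)
  seeds <- child_seeds(seed, m)
  purrr::map(seeds, function(s)
    simulate_neuron(params, init = init, field = field, seed = s))
}

#' Simulate a dataset and return only its morphometrics
#'
#' Fast path used by calibration and sensitivity analysis: neurons are
#' grown and reduced to the four quantities of interest without
#' materialising the trees in R.
#'
#' @inheritParams simulate_dataset
#' @param selection `"all"`, `"apical"` or `"basal"` subtree selection.
#' @return An `m x 4` QoI tibble (see [compute_morphometrics()]).
#' @export
simulate_qois <- function(params, m, init = NULL, field = guidance_field(),
                          seed = 1, selection = c("all", "apical", "basal")) {
  selection <- match.arg(selection)
  init <- default_init(params, init)
  validate_neuron_tree(init)
  mat <- cpp_simulate_qois(tree_to_cpp(init), unclass(params),
                           field_gradient_vector(field),
                           child_seeds(seed, m), selection_code(selection))
  colnames(mat) <- qoi_names()
  as_tibble(mat)
}

selection_code <- function(selection) {
  switch(selection, all = 0L, basal = 3L, apical = 4L)
}

#' Build a growth-model simulator over a parameter subspace
#'
#' Returns a function `f(theta, m, seed)` that simulates `m` neurons with
#' the components of `theta` substituted into `base_params` (by
#' `par_names`) and returns their QoI matrix -- the simulator interface
#' used by [run_smcabc()] and [expected_qois()]. A tree exceeding
#' `max_nodes` yields `NULL` ("no dataset"), which calibration treats as
#' an automatic miss.
#'
#' @param base_params A [model_params()] object supplying fixed parameters.
#' @param par_names Names of the calibrated parameters, in `theta` order.
#' @param selection QoI subtree selection.
#' @param init,field As in [simulate_neuron()].
#' @return A function `(theta, m, seed) -> m x 4` matrix or `NULL`.
#' @export
growth_simulator <- function(base_params, par_names = c("p_bra", "R", "v"),
                             selection = c("all", "apical", "basal"),
                             init = NULL, field = guidance_field()) {
  selection <- match.arg(selection)
  init <- default_init(base_params, init)
  validate_neuron_tree(init)
  init_mat <- tree_to_cpp(init)
  grad <- field_gradient_vector(field)
  sel <- selection_code(selection)
  force(par_names)
  function(theta, m, seed) {
    p <- unclass(base_params)
    p[par_names] <- as.list(as.numeric(theta))
    out <- tryCatch(
      cpp_simulate_qois(init_mat, p, grad, child_seeds(seed, m), sel),
      error = function(e) {
        if (grepl("max_nodes", conditionMessage(e))) NULL else stop(e)
      }
    )
    if (!is.null(out)) colnames(out) <- qoi_names()
    out
  }
}
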