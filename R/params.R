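#' Growth-rule parameters for the resource-driven neuron models
#'
#' Bundles and validates the parameters of the two agent-based growth rules.
#' Model 1 bifurcates symmetrically: a branching tip is replaced by two
#' daughters that both inherit the mother's resource. Model 2 side-branches
#' asymmetrically: the mother continues in a straight line (inheriting
#' resource and orientation) and sprouts a lateral daughter initialised to
#' the fixed resource `r_0`; in addition, every agent in Model 2 loses `R`
#' resource per step (global decay) until it reaches the floor `r_min - R`.
#'
#' All rates are parametrised per time step: `p_bra` is the branching
#' probability per tip per step, `v` the elongation length per step and `R`
#' the resource consumed per elongation (and, in Model 2, per decay event).
#'
#' The defaults describe an apical-like Model 2 neuron: side branches are
#' short-lived relative to the main branch because
#' `p_bra * (r_0 - r_min) / (2 R) < 1` keeps the lateral branching cascade
#' subcritical, while the main branch's resource lifetime
#' `(r_init - r_min) / (2 R)` (about 630 steps) exceeds the simulated
#' window, so the window -- not resource exhaustion -- terminates apical
#' growth. The latter anchors the scale of the per-step rates: without it
#' the rules admit an exact `(p_bra, R, v) -> (c p_bra, c R, c v)`
#' degeneracy of all four QoIs (see the methods vignette). Model 1
#' defaults are chosen so that basal trees go through a handful of
#' bifurcation generations before their resource is exhausted.
#'
#' @param model_id 1 (symmetric bifurcation) or 2 (asymmetric side branching).
#' @param p_bra Branching probability per tip per step, in `[0, 1]`.
#' @param R Resource consumed per elongation or decay event (resource units).
#' @param v Elongation length per step (length units).
#' @param r_min Resource threshold below which an agent is idle.
#' @param r_init Resource assigned to the initial neurite stubs.
#' @param r_0 Resource assigned to a newly created side branch (Model 2).
#' @param dt Duration of one step (time units); rules are per step, so `dt`
#'   only fixes the meaning of the total time `T = n_steps * dt`.
#' @param n_steps Number of simulated steps.
#' @param w_rand,w_old,w_grad Non-negative weights of the random,
#'   persistence and gradient components of the elongation direction.
#' @param l_max Maximum agent length before a collinear split into equal
#'   halves (length units).
#' @param theta_bifurcate_deg Half-angle between Model 1 daughters (degrees).
#' @param theta_side_deg Deflection of a Model 2 side branch (degrees).
#' @param max_nodes Hard cap on agents per neuron; exceeding it signals an
#'   error (guards against supercritical parameter combinations).
#'
#' @return A validated list of class `"model_params"`.
#' @examples
#' p <- model_params(model_id = 2, p_bra = 0.038, R = 0.00071, v = 100)
#' p$n_steps
#' @export
model_params <- function(model_id = 2,
                         p_bra = if (model_id == 2) 0.038 else 0.01,
                         R = if (model_id == 2) 0.00071 else 0.004,
                         v = if (model_id == 2) 100 else 50,
                         r_min = 0.1,
                         r_init = 1.0,
                         r_0 = 0.12,
                         dt = 1,
                         n_steps = 500,
                         w_rand = 0.4,
                         w_old = 0.5,
                         w_grad = 0.1,
                         l_max = 10,
                         theta_bifurcate_deg = 30,
                         theta_side_deg = 60,
                         max_nodes = 100000L) {
  p <- list(
    model_id = as.integer(model_id), p_bra = p_bra, R = R, v = v,
    r_min = r_min, r_init = r_init, r_0 = r_0, dt = dt,
    n_steps = as.integer(n_steps), w_rand = w_rand, w_old = w_old,
    w_grad = w_grad, l_max = l_max,
    theta_bifurcate_deg = theta_bifurcate_deg,
    theta_side_deg = theta_side_deg, max_nodes = as.integer(max_nodes)
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  stopifnot(is.list(p))
  if (!p$model_id %in% c(1L, 2L)) abort("`model_id` must be 1 or 2")
  if (p$p_bra < 0 || p$p_bra > 1) abort("`p_bra` must lie in [0, 1]")
  if (p$v < 0) abort("`v` must be >= 0")
  if (p$R < 0) abort("`R` must be >= 0")
  if (p$r_init <= p$r_min) abort("`r_init` must exceed `r_min`")
  if (p$l_max <= 0) abort("`l_max` must be positive")
  w <- c(p$w_rand, p$w_old, p$w_grad)
  if (any(w < 0)) abort("direction weights must be non-negative")
  if (sum(w) == 0) abort("direction weights must not all be zero")
  if (p$n_steps < 0) abort("`n_steps` must be >= 0")
  if (p$model_id == 2L && p$r_0 <= p$r_min)
    warn("`r_0` <= `r_min`: side branches are born idle and will be pruned")
  invisible(p)
}

#' Replace selected growth parameters
#'
#' Convenience for building simulators over a parameter subspace: returns a
#' copy of `params` with the named entries replaced and re-validated.
#'
#' @param params A [model_params()] object.
#' @param ... Named scalar replacements, e.g. `p_bra = 0.05`.
#' @return A `"model_params"` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  p <- modifyList(unclass(params), repl)
  p$model_id <- as.integer(p$model_id)
  p$n_steps <- as.integer(p$n_steps)
  p$max_nodes <- as.integer(p$max_nodes)
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> model %d: p_bra=%g R=%g v=%g r_min=%g r_init=%g r_0=%g n_steps=%d\n",
    x$model_id, x$p_bra, x$R, x$v, x$r_min, x$r_init, x$r_0, x$n_steps
  ))
  invisible(x)
}
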