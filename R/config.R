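#' Read a structured-text (YAML) configuration
#'
#' Configuration files collect the keys understood by the command-line
#' interface and the high-level workflows: the `model` block
#' (`model_id`, `p_bra`, `R`, `v`, `r_min`, `r_init`, `r_0`, `dt`,
#' `n_steps`, `w_rand`, `w_old`, `w_grad`, `l_max`,
#' `theta_bifurcate_deg`, `theta_side_deg`), the `init` block
#' (`n_apical_stubs`, `n_basal_stubs`, `stub_length`), the `distance`
#' block (`name`, `gamma`, `n_projections`, `standardize`), the `smc`
#' block (keys of [smc_config()]), the `sa` block (`n_base`,
#' `m_replicates`, `n_bootstrap`), `prior` (`names`, `lower`, `upper`),
#' `selection` and `seed`. Two named profiles ship with the package:
#' `"desk"` (N = 256, M' = 25, budget 5e5) and `"paper"`
#' (N = 1024, M' = 50, budget 5e7).
#'
#' @param path YAML file path, or a profile name (`"desk"`, `"paper"`).
#' @return A nested configuration list.
#' @export
read_config <- function(path) {
  if (path %in% c("desk", "paper"))
    path <- system.file("configs", paste0(path, ".yaml"), package = "abcgrow")
  if (!file.exists(path))
    abort(sprintf("no such config: %s", path), class = "abcgrow_config_error")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a YAML mapping",
                           class = "abcgrow_config_error")
  cfg
}

config_params <- function(cfg) {
  m <- cfg$model %||% list()
  do.call(model_params, m)
}

config_init <- function(cfg, params) {
  i <- cfg$init %||% list()
  init_neuron(
    n_apical = i$n_apical_stubs %||% if (params$model_id == 2) 1 else 0,
    n_basal = i$n_basal_stubs %||% if (params$model_id == 2) 0 else 3,
    stub_length = i$stub_length %||% 10,
    r_init = params$r_init
  )
}

config_distance <- function(cfg) {
  d <- cfg$distance %||% list()
  make_distance(d$name %||% "wasserstein",
                gamma = d$gamma %||% 0.5,
                n_projections = d$n_projections %||% 50)
}

config_prior <- function(cfg) {
  p <- cfg$prior
  if (is.null(p)) abort("config lacks a `prior` block",
                        class = "abcgrow_config_error")
  prior_uniform(unlist(p$lower), unlist(p$upper), unlist(p$names))
}

config_smc <- function(cfg, seed = NULL) {
  s <- cfg$smc %||% list()
  if (!is.null(seed)) s$seed <- seed
  if (!is.null(cfg$distance$standardize)) s$standardize <- cfg$distance$standardize
  do.call(smc_config, s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
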