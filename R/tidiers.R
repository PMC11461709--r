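#' Tidy a fitted SMC-ABC posterior
#'
#' One row per calibrated parameter with weighted posterior summaries.
#'
#' @param x An `"abc_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `map`,
#'   `q05`, `q50`, `q95`.
#' @export
tidy.abc_fit <- function(x, ...) {
  theta <- as_qoi_matrix(x$particles[x$prior$name])
  w <- x$particles$weight
  mp <- map_estimate(x)
  rows <- purrr::map(seq_len(ncol(theta)), function(j) {
    v <- theta[, j]
    mu <- sum(w * v)
    tibble(
      parameter = colnames(theta)[j],
      mean = mu,
      sd = sqrt(sum(w * (v - mu)^2)),
      map = unname(mp[j]),
      q05 = weighted_quantile(v, w, 0.05),
      q50 = weighted_quantile(v, w, 0.5),
      q95 = weighted_quantile(v, w, 0.95)
    )
  })
  dplyr::bind_rows(rows)
}

#' Glance at a fitted SMC-ABC posterior
#'
#' @param x An `"abc_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_particles`, `n_iterations`, `final_eps`,
#'   `ess`, `acceptance_rate`, `cum_sims`.
#' @export
glance.abc_fit <- function(x, ...) {
  last <- if (nrow(x$trace)) x$trace[nrow(x$trace), ] else
    tibble(epsilon = Inf, acceptance_rate = NA_real_)
  tibble(
    n_particles = nrow(x$particles),
    n_iterations = x$n_iterations,
    final_eps = last$epsilon,
    ess = ess(x$particles$weight),
    acceptance_rate = last$acceptance_rate,
    cum_sims = x$cum_sims
  )
}

#' Tidy a Sobol sensitivity result
#'
#' @param x A `"sobol_result"` object.
#' @param ... Unused.
#' @return Long tibble with `parameter`, `output`, `index` (`"S1"` /
#'   `"S_tot"`), `estimate`, `ci_half_width`.
#' @export
tidy.sobol_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(parameter = x$parameter, output = x$output, index = "S1",
           estimate = x$s1, ci_half_width = x$s1_ci),
    tibble(parameter = x$parameter, output = x$output, index = "S_tot",
           estimate = x$s_tot, ci_half_width = x$s_tot_ci)
  )
}

#' Glance at a Sobol sensitivity result
#'
#' @param x A `"sobol_result"` object.
#' @param ... Unused.
#' @return One-row tibble with counts and the maximal total-effect index.
#' @export
glance.sobol_result <- function(x, ...) {
  tibble(
    n_parameters = length(unique(x$parameter)),
    n_outputs = length(unique(x$output)),
    max_s_tot = max(x$s_tot),
    any_zero_variance = any(x$zero_variance)
  )
}
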