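#' External guidance cue
#'
#' A scalar field `phi(x, t)` whose gradient biases tip elongation. The
#' built-in cue is linear and time-invariant, `phi(x) = <x, direction>`,
#' with the constant gradient `direction` -- the simplest attractant
#' consistent with apical growth away from the soma.
#'
#' @param direction Gradient vector of the linear field (need not be unit).
#' @return An object of class `"guidance_field"` with elements `value(x, t)`
#'   and `gradient(x, t)` (both accept a length-3 point or an `n x 3`
#'   matrix) and the constant `direction`.
#' @examples
#' f <- guidance_field(c(0, 0, 1))
#' f$value(c(1, 2, 3), 0)
#' f$gradient(c(1, 2, 3), 0)
#' @export
guidance_field <- function(direction = c(0, 0, 1)) {
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3, all(is.finite(direction)))
  g <- direction
  structure(
    list(
      value = function(x, t = 0) {
        x <- rbind(x)
        drop(x %*% g)
      },
      gradient = function(x, t = 0) {
        x <- rbind(x)
        matrix(g, nrow(x), 3, byrow = TRUE)
      },
      direction = g
    ),
    class = "guidance_field"
  )
}

field_gradient_vector <- function(field) {
  if (inherits(field, "guidance_field")) return(field$direction)
  if (is.numeric(field) && length(field) == 3) return(as.numeric(field))
  abort("`field` must be a guidance_field or a length-3 gradient vector")
}
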