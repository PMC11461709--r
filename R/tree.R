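#' Initial neuron configuration
#'
#' Builds the starting tree for a growth simulation: a spherical soma at
#' `soma_position` plus short neurite stubs carrying the initial resource.
#' Apical stubs (SWC type 4) point along +z; basal stubs (type 3) point
#' into the -z hemisphere at a fixed polar angle with evenly spaced
#' azimuths, so the initial configuration is deterministic.
#'
#' Stub cylinders start at the soma centre (the SWC convention assigns the
#' cylinder between a parent and child point to the child record, and the
#' stub's parent record is the soma centre).
#'
#' @param n_apical,n_basal Number of apical / basal stubs.
#' @param stub_length Length of each stub (length units).
#' @param soma_position Length-3 soma centre.
#' @param soma_radius Soma radius (length units).
#' @param r_init Resource assigned to each stub.
#' @param diameter Neurite diameter carried by all agents (length units).
#' @return A `neuron_tree` tibble (one row per agent, soma first).
#' @examples
#' init_neuron(n_apical = 1)
#' @export
init_neuron <- function(n_apical = 1, n_basal = 0, stub_length = 10,
                        soma_position = c(0, 0, 0), soma_radius = 7.5,
                        r_init = 1.0, diameter = 1.0) {
  stopifnot(n_apical >= 0, n_basal >= 0, n_apical + n_basal >= 1,
            stub_length > 0)
  dirs <- list()
  types <- integer(0)
  if (n_apical > 0) {
    for (i in seq_len(n_apical)) {
      phi <- 2 * pi * (i - 1) / n_apical
      # single apical stub points straight up; several fan out slightly
      th <- if (n_apical == 1) 0 else 15 * pi / 180
      dirs <- c(dirs, list(c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))))
      types <- c(types, 4L)
    }
  }
  if (n_basal > 0) {
    th <- 135 * pi / 180  # polar angle into the lower hemisphere
    for (i in seq_len(n_basal)) {
      phi <- 2 * pi * (i - 1) / n_basal
      dirs <- c(dirs, list(c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))))
      types <- c(types, 3L)
    }
  }
  n <- length(dirs)
  soma <- tibble(
    id = 1L, kind = "soma", type = 1L, parent = NA_integer_,
    start_x = soma_position[1], start_y = soma_position[2], start_z = soma_position[3],
    end_x = soma_position[1], end_y = soma_position[2], end_z = soma_position[3],
    diameter = 2 * soma_radius, resource = NA_real_,
    orient_x = 0, orient_y = 0, orient_z = 0
  )
  stubs <- purrr::map2_dfr(dirs, seq_len(n), function(d, i) {
    tibble(
      id = i + 1L, kind = "neurite", type = types[i], parent = 1L,
      start_x = soma_position[1], start_y = soma_position[2], start_z = soma_position[3],
      end_x = soma_position[1] + stub_length * d[1],
      end_y = soma_position[2] + stub_length * d[2],
      end_z = soma_position[3] + stub_length * d[3],
      diameter = diameter, resource = r_init,
      orient_x = d[1], orient_y = d[2], orient_z = d[3]
    )
  })
  new_neuron_tree(dplyr::bind_rows(soma, stubs))
}

new_neuron_tree <- function(x) {
  structure(as_tibble(x), class = c("neuron_tree", class(as_tibble(x))))
}

#' Validate a neuron tree
#'
#' Checks the structural invariants of a `neuron_tree`: unique ids, a
#' single soma root, parents preceding children, acyclicity (implied by
#' the ordering), and coincidence of each child's start point with its
#' parent's end point.
#'
#' @param tree A `neuron_tree` tibble.
#' @param tol Tolerance for endpoint coincidence.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_neuron_tree <- function(tree, tol = 1e-6) {
  stopifnot(is.data.frame(tree))
  if (anyDuplicated(tree$id)) abort("duplicate agent ids")
  soma <- tree[tree$kind == "soma", ]
  if (nrow(soma) != 1) abort("tree must contain exactly one soma")
  if (!is.na(soma$parent)) abort("soma must be the root")
  neur <- tree[tree$kind == "neurite", ]
  if (nrow(neur) == 0) return(invisible(tree))
  idx <- match(neur$parent, tree$id)
  if (anyNA(idx)) abort("dangling parent id")
  pos <- match(neur$id, tree$id)
  if (any(idx >= pos)) abort("parents must precede children")
  pend <- cbind(tree$end_x[idx], tree$end_y[idx], tree$end_z[idx])
  cstart <- cbind(neur$start_x, neur$start_y, neur$start_z)
  gap <- sqrt(rowSums((pend - cstart)^2))
  soma_par <- tree$kind[idx] == "soma"
  if (any(gap[!soma_par] > tol))
    abort("child start does not coincide with parent end")
  invisible(tree)
}

# tree tibble -> 13-column matrix for the C++ core (neurites only)
tree_to_cpp <- function(tree) {
  neur <- tree[tree$kind == "neurite", ]
  ids <- neur$id
  par <- match(neur$parent, ids)   # NA where parent is the soma
  par[is.na(par)] <- 0L
  if (anyNA(neur$resource))
    abort("neurite agents must carry a numeric `resource` to be simulated")
  cbind(
    neur$start_x, neur$start_y, neur$start_z,
    neur$end_x, neur$end_y, neur$end_z,
    neur$orient_x, neur$orient_y, neur$orient_z,
    neur$resource, par, neur$type, neur$diameter
  )
}

# 13-column matrix from the C++ core -> tree tibble (soma row prepended)
tree_from_cpp <- function(mat, soma_row) {
  n <- nrow(mat)
  if (n == 0) return(new_neuron_tree(soma_row))
  nodes <- tibble(
    id = seq_len(n) + 1L, kind = "neurite", type = as.integer(mat[, 12]),
    parent = ifelse(mat[, 11] == 0, 1L, as.integer(mat[, 11]) + 1L),
    start_x = mat[, 1], start_y = mat[, 2], start_z = mat[, 3],
    end_x = mat[, 4], end_y = mat[, 5], end_z = mat[, 6],
    diameter = mat[, 13], resource = mat[, 10],
    orient_x = mat[, 7], orient_y = mat[, 8], orient_z = mat[, 9]
  )
  new_neuron_tree(dplyr::bind_rows(soma_row, nodes))
}

soma_row_of <- function(tree) tree[tree$kind == "soma", ]

#' Agent cylinder lengths
#'
#' @param tree A `neuron_tree`.
#' @return Numeric vector of neurite agent lengths (soma excluded).
#' @export
agent_lengths <- function(tree) {
  neur <- tree[tree$kind == "neurite", ]
  sqrt((neur$end_x - neur$start_x)^2 + (neur$end_y - neur$start_y)^2 +
         (neur$end_z - neur$start_z)^2)
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d agents (%d neurite), total length %.2f\n",
              nrow(x), sum(x$kind == "neurite"), sum(agent_lengths(x))))
  NextMethod()
}
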