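#' Write a neuron to an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), whitespace
#' separated with `#` comments. The soma is record 1 (type 1, parent -1);
#' each neurite agent contributes its endpoint, with basal dendrites typed
#' 3 and apical dendrites typed 4. Ids are contiguous from 1 in
#' parent-before-child order.
#'
#' @param tree A `neuron_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  validate_neuron_tree(tree)
  soma <- soma_row_of(tree)
  neur <- tree[tree$kind == "neurite", ]
  ids <- c(soma$id, neur$id)
  newid <- match(ids, ids)  # 1..n in current order
  lines <- c(
    "# SWC export",
    "# id type x y z radius parent",
    sprintf("%d %d %.8g %.8g %.8g %.8g %d", 1L, 1L,
            soma$end_x, soma$end_y, soma$end_z, soma$diameter / 2, -1L)
  )
  if (nrow(neur) > 0) {
    par <- match(neur$parent, ids)
    lines <- c(lines, sprintf(
      "%d %d %.8g %.8g %.8g %.8g %d",
      match(neur$id, ids), neur$type, neur$end_x, neur$end_y, neur$end_z,
      neur$diameter / 2, par
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a neuron from an SWC file
#'
#' Reconstructs a `neuron_tree` from standard SWC: the single type-1 root
#' record becomes the soma; every other record becomes a cylindrical agent
#' from its parent's point to its own point. Malformed input (non-numeric
#' fields, dangling or forward parent references, multiple roots) raises a
#' format error naming the offending line.
#'
#' @param path SWC file path.
#' @param resource Resource value assigned to the agents read (`NA` by
#'   default; assign e.g. `r_init` before re-simulating).
#' @return A `neuron_tree` tibble.
#' @export
read_swc <- function(path, resource = NA_real_) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0) abort(sprintf("%s: no records", path))
  seen <- integer(0)
  recs <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(trimws(raw[ln]), "\\s+")[[1]]
    if (length(fields) != 7)
      abort(sprintf("%s line %d: expected 7 fields, got %d", path, ln,
                    length(fields)))
    val <- suppressWarnings(as.numeric(fields))
    if (anyNA(val))
      abort(sprintf("%s line %d: non-numeric field", path, ln))
    id <- as.integer(val[1]); parent <- as.integer(val[7])
    if (id < 1 || id %in% seen)
      abort(sprintf("%s line %d: invalid or duplicate id %d", path, ln, id))
    if (parent != -1 && !(parent %in% seen))
      abort(sprintf("%s line %d: parent %d not yet defined", path, ln, parent))
    seen <- c(seen, id)
    recs[[k]] <- val
  }
  m <- do.call(rbind, recs)
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  roots <- which(m[, "parent"] == -1)
  if (length(roots) != 1)
    abort(sprintf("%s: expected exactly one root, found %d", path,
                  length(roots)))
  root <- roots[1]
  if (m[root, "type"] != 1)
    abort(sprintf("%s: root record must be the soma (type 1)", path))
  extra_soma <- which(m[, "type"] == 1)
  if (length(extra_soma) > 1)
    abort(sprintf("%s: multi-point somata are not supported", path))

  rx <- unname(m[root, "x"]); ry <- unname(m[root, "y"])
  rz <- unname(m[root, "z"])
  soma <- tibble(
    id = 1L, kind = "soma", type = 1L, parent = NA_integer_,
    start_x = rx, start_y = ry, start_z = rz,
    end_x = rx, end_y = ry, end_z = rz,
    diameter = 2 * unname(m[root, "radius"]), resource = NA_real_,
    orient_x = 0, orient_y = 0, orient_z = 0
  )
  others <- m[-root, , drop = FALSE]
  if (nrow(others) == 0) return(new_neuron_tree(soma))
  pid <- match(others[, "parent"], m[, "id"])
  px <- m[pid, "x"]; py <- m[pid, "y"]; pz <- m[pid, "z"]
  dx <- others[, "x"] - px; dy <- others[, "y"] - py; dz <- others[, "z"] - pz
  nn <- sqrt(dx^2 + dy^2 + dz^2)
  nn[nn < 1e-12] <- 1
  # agent ids follow record order; parent maps to agent id or soma (1)
  newid <- seq_len(nrow(others)) + 1L
  oldid <- others[, "id"]
  par_agent <- match(others[, "parent"], oldid)
  nodes <- tibble(
    id = newid, kind = "neurite", type = as.integer(others[, "type"]),
    parent = ifelse(is.na(par_agent), 1L, newid[par_agent]),
    start_x = unname(px), start_y = unname(py), start_z = unname(pz),
    end_x = unname(others[, "x"]), end_y = unname(others[, "y"]),
    end_z = unname(others[, "z"]),
    diameter = 2 * unname(others[, "radius"]), resource = resource,
    orient_x = unname(dx / nn), orient_y = unname(dy / nn),
    orient_z = unname(dz / nn)
  )
  out <- new_neuron_tree(dplyr::bind_rows(soma, nodes))
  validate_neuron_tree(out)
  out
}
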