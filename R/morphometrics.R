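qoi_names <- function() {
  c("m1_n_segments", "m2_mean_seg_len", "m3_std_seg_len", "m4_total_len")
}

#' Decompose a neuron into unbranched sections
#'
#' A *section* (segment) is a maximal unbranched path between topological
#' nodes: soma attachments, branch points and tips. Its length is the sum
#' of the lengths of its constituent cylindrical agents, so the
#' decomposition is invariant to the simulator's collinear splitting of
#' long cylinders.
#'
#' @param tree A `neuron_tree`.
#' @param selection `"all"`, `"apical"` (SWC type 4) or `"basal"` (type 3).
#' @return A tibble with one row per section: `section_id`, `n_agents`,
#'   `length`, and `agent_ids` (list-column of the member agent ids, in
#'   proximal-to-distal order).
#' @export
extract_sections <- function(tree, selection = c("all", "apical", "basal")) {
  selection <- match.arg(selection)
  validate_neuron_tree(tree)
  neur <- tree[tree$kind == "neurite", ]
  if (selection != "all")
    neur <- neur[neur$type == selection_code(selection), ]
  if (nrow(neur) == 0)
    return(tibble(section_id = integer(), n_agents = integer(),
                  length = numeric(), agent_ids = list()))
  # children counted within the selection
  nchild <- table(factor(neur$parent, levels = neur$id))
  in_sel <- neur$parent %in% neur$id
  lens <- sqrt((neur$end_x - neur$start_x)^2 + (neur$end_y - neur$start_y)^2 +
                 (neur$end_z - neur$start_z)^2)
  # heads: agents whose parent is outside the selection or is a branch point
  par_idx <- match(neur$parent, neur$id)
  head <- !in_sel | nchild[par_idx] >= 2
  sec_of <- integer(nrow(neur))
  next_id <- 0L
  for (i in seq_len(nrow(neur))) {  # parents precede children
    if (head[i]) {
      next_id <- next_id + 1L
      sec_of[i] <- next_id
    } else {
      sec_of[i] <- sec_of[par_idx[i]]
    }
  }
  out <- tibble(sec = sec_of, id = neur$id, len = lens) |>
    dplyr::group_by(.data$sec) |>
    dplyr::summarise(n_agents = dplyr::n(), length = sum(.data$len),
                     agent_ids = list(.data$id), .groups = "drop") |>
    dplyr::rename(section_id = "sec")
  out[out$length > 1e-9, , drop = FALSE]
}

#' Morphometric quantities of interest of one neuron
#'
#' Reduces a neuron to the four-dimensional QoI vector used throughout the
#' calibration: number of segments (M1), mean segment length (M2),
#' standard deviation of segment length (M3, population convention by
#' default) and total dendritic length (M4). Segments are unbranched
#' sections (see [extract_sections()]); the soma is excluded.
#'
#' @inheritParams extract_sections
#' @param sd `"population"` (divide by n) or `"sample"` (divide by n - 1).
#' @return A 1 x 4 tibble with columns `m1_n_segments`, `m2_mean_seg_len`,
#'   `m3_std_seg_len`, `m4_total_len`.
#' @examples
#' p <- model_params(model_id = 2, n_steps = 50)
#' compute_morphometrics(simulate_neuron(p, seed = 1))
#' @export
compute_morphometrics <- function(tree, selection = c("all", "apical", "basal"),
                                  sd = c("population", "sample")) {
  selection <- match.arg(selection)
  sd <- match.arg(sd)
  secs <- extract_sections(tree, selection)
  n <- nrow(secs)
  if (n == 0) abort("no sections in the selected subtree")
  mu <- mean(secs$length)
  v <- sum((secs$length - mu)^2) / if (sd == "population") n else max(n - 1, 1)
  tibble(
    m1_n_segments = as.numeric(n),
    m2_mean_seg_len = mu,
    m3_std_seg_len = sqrt(v),
    m4_total_len = sum(secs$length)
  )
}

#' QoI matrix of a dataset of neurons
#'
#' @param x A list of `neuron_tree` objects or a character vector of SWC
#'   file paths.
#' @inheritParams compute_morphometrics
#' @return A QoI tibble with one row per neuron (input order) and a
#'   `neuron` label column first.
#' @export
dataset_qois <- function(x, selection = c("all", "apical", "basal"),
                         sd = c("population", "sample")) {
  selection <- match.arg(selection)
  sd <- match.arg(sd)
  if (is.character(x)) {
    labels <- basename(x)
    trees <- purrr::map(x, read_swc)
  } else {
    labels <- if (!is.null(names(x))) names(x) else
      sprintf("neuron_%04d", seq_along(x))
    trees <- x
  }
  rows <- purrr::map2(trees, labels, function(tr, lab) {
    tryCatch(compute_morphometrics(tr, selection, sd),
             error = function(e) abort(sprintf("neuron '%s': %s", lab,
                                               conditionMessage(e))))
  })
  dplyr::bind_cols(tibble(neuron = labels), dplyr::bind_rows(rows))
}

# coerce a QoI tibble / data frame / matrix to a plain numeric matrix
as_qoi_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  as.matrix(x[, num, drop = FALSE])
}

#' Write a QoI table to CSV
#'
#' @param qois A QoI tibble (label columns are dropped).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qois <- function(qois, path) {
  m <- as_qoi_matrix(qois)
  write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a QoI table from CSV
#'
#' @param path CSV file with the `m1_n_segments,...,m4_total_len` header.
#' @return A QoI tibble.
#' @export
read_qois <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}
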