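# Small fixtures shared across tests; everything is generated in code.

tiny_params <- function(model_id = 2, n_steps = 60, ...) {
  model_params(model_id = model_id, n_steps = n_steps, ...)
}

# hand-built Y-shaped tree: one stem of length 2 splitting into two
# daughters of length 1 each, all axis-aligned
y_tree <- function() {
  rows <- tibble::tibble(
    id = 1:4,
    kind = c("soma", "neurite", "neurite", "neurite"),
    type = c(1L, 4L, 4L, 4L),
    parent = c(NA, 1L, 2L, 2L),
    start_x = c(0, 0, 0, 0), start_y = c(0, 0, 0, 0),
    start_z = c(0, 0, 2, 2),
    end_x = c(0, 0, 1, -1), end_y = c(0, 0, 0, 0),
    end_z = c(0, 2, 2, 2),
    diameter = c(15, 1, 1, 1),
    resource = c(NA, 1, 1, 1),
    orient_x = c(0, 0, 1, -1), orient_y = 0,
    orient_z = c(0, 1, 0, 0)
  )
  abcgrow:::new_neuron_tree(rows)
}

# unbranched chain of `n` collinear unit agents along +z
chain_tree <- function(n = 5) {
  soma <- tibble::tibble(
    id = 1L, kind = "soma", type = 1L, parent = NA_integer_,
    start_x = 0, start_y = 0, start_z = 0, end_x = 0, end_y = 0, end_z = 0,
    diameter = 15, resource = NA_real_,
    orient_x = 0, orient_y = 0, orient_z = 0
  )
  nodes <- tibble::tibble(
    id = seq_len(n) + 1L, kind = "neurite", type = 4L,
    parent = seq_len(n),
    start_x = 0, start_y = 0, start_z = seq_len(n) - 1,
    end_x = 0, end_y = 0, end_z = seq_len(n),
    diameter = 1, resource = 1,
    orient_x = 0, orient_y = 0, orient_z = 1
  )
  abcgrow:::new_neuron_tree(dplyr::bind_rows(soma, nodes))
}

# random binary tree with `n_branch` bifurcations, unit-ish segment
# lengths; built agent by agent so the brute-force section oracle below
# stays independent of extract_sections()
random_tree <- function(n_branch = 5, seed = 1) {
  set.seed(seed)
  tr <- init_neuron(n_apical = 1, stub_length = runif(1, 0.5, 2))
  for (b in seq_len(n_branch)) {
    neur <- tr[tr$kind == "neurite", ]
    nchild <- table(factor(neur$parent, levels = neur$id))
    tips <- neur$id[nchild[as.character(neur$id)] == 0]
    mother <- tr[tr$id == sample(rep(tips, 2), 1), ]  # rep() guards n=1
    for (k in 1:2) {
      d <- abcgrow:::random_unit_vector()
      len <- runif(1, 0.5, 2)
      child <- mother
      child$id <- max(tr$id) + 1L
      child$parent <- mother$id
      child$start_x <- mother$end_x; child$start_y <- mother$end_y
      child$start_z <- mother$end_z
      child$end_x <- mother$end_x + len * d[1]
      child$end_y <- mother$end_y + len * d[2]
      child$end_z <- mother$end_z + len * d[3]
      child$orient_x <- d[1]; child$orient_y <- d[2]; child$orient_z <- d[3]
      tr <- abcgrow:::new_neuron_tree(dplyr::bind_rows(tr, child))
    }
  }
  tr
}

# brute-force section decomposition: enumerate root-to-tip paths and cut
# them at branch points
brute_sections <- function(tree) {
  neur <- tree[tree$kind == "neurite", ]
  nchild <- table(factor(neur$parent, levels = neur$id))
  deg <- as.integer(nchild[as.character(neur$id)])
  len_of <- function(id) {
    r <- neur[neur$id == id, ]
    sqrt((r$end_x - r$start_x)^2 + (r$end_y - r$start_y)^2 +
           (r$end_z - r$start_z)^2)
  }
  tips <- neur$id[deg == 0]
  segs <- list()
  for (tip in tips) {
    path <- integer(0)
    id <- tip
    repeat {
      path <- c(id, path)
      par <- neur$parent[neur$id == id]
      if (!(par %in% neur$id)) break
      id <- par
    }
    # cut path after any agent whose node is a branch point
    cut_after <- vapply(path, function(i) deg[match(i, neur$id)] >= 2, logical(1))
    start <- 1
    for (i in seq_along(path)) {
      if (cut_after[i] || i == length(path)) {
        segs[[length(segs) + 1]] <- path[start:i]
        start <- i + 1
      }
    }
  }
  keys <- vapply(segs, function(s) paste(s, collapse = "-"), character(1))
  segs <- segs[!duplicated(keys)]
  lengths <- vapply(segs, function(s) sum(vapply(s, len_of, numeric(1))),
                    numeric(1))
  sort(lengths)
}

gaussian_toy_simulator <- function(theta, m, seed) {
  set.seed(as.integer(seed %% 2147483647))
  matrix(rnorm(m, theta[1], 1), ncol = 1)
}
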