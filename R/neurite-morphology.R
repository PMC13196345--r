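#' Construct a neuron tree from a node table
#'
#' @param nodes Tibble/data frame with SWC columns `id`, `type`, `x`, `y`,
#'   `z` (micrometres), `radius`, `parent` (-1 for the soma/root).
#' @return Object of class `neuron_tree` with `nodes` (tibble) and `root`
#'   (the root node id).
#' @export
neuron_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes))) {
    abort("nodes need columns id, type, x, y, z, radius, parent",
          class = "mmpscreen_format_error")
  }
  if (anyDuplicated(nodes$id)) {
    abort(paste0("duplicate node ids: ",
                 paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")),
          class = "mmpscreen_format_error")
  }
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1) {
    abort(paste0("tree must have exactly one root, found: ",
                 paste(roots, collapse = ", ")),
          class = "mmpscreen_format_error")
  }
  dangling <- setdiff(nodes$parent, c(-1, nodes$id))
  if (length(dangling) > 0) {
    abort(paste0("dangling parent id(s): ", paste(dangling, collapse = ", ")),
          class = "mmpscreen_format_error")
  }
  # cycle check: every node must reach the root
  parent_of <- setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- character(0)
    cur <- id
    while (cur != -1) {
      key <- as.character(cur)
      if (key %in% seen) {
        abort(paste0("cycle involving node ", id),
              class = "mmpscreen_format_error")
      }
      seen <- c(seen, key)
      cur <- parent_of[[key]]
    }
  }
  structure(list(nodes = nodes, root = roots), class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree: %d nodes, %d terminals, total length %.1f um>\n",
              nrow(x$nodes), terminal_points(x), total_length(x)))
  invisible(x)
}

#' Read an SWC neuron reconstruction
#'
#' Standard 7-column SWC text (id, type, x, y, z, radius, parent; `#`
#' comments ignored). The soma is the unique node with parent -1.
#'
#' @param path SWC file path.
#' @return A [neuron_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort(paste0("empty SWC file: ", path), class = "mmpscreen_format_error")
  }
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 7)) {
    abort(paste0("malformed SWC rows (need 7 columns) at line(s): ",
                 paste(which(lengths(fields) != 7), collapse = ", ")),
          class = "mmpscreen_format_error")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(!is.finite(m))) {
    abort("non-numeric SWC fields", class = "mmpscreen_format_error")
  }
  neuron_tree(tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  ))
}

#' Write a neuron tree as SWC
#'
#' Coordinates are written with full (round-trip) precision.
#'
#' @param tree A [neuron_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes
  lines <- sprintf("%d %d %s %s %s %s %d", n$id, n$type,
                   format(n$x, digits = 17, trim = TRUE, scientific = FALSE),
                   format(n$y, digits = 17, trim = TRUE, scientific = FALSE),
                   format(n$z, digits = 17, trim = TRUE, scientific = FALSE),
                   format(n$radius, digits = 17, trim = TRUE, scientific = FALSE),
                   n$parent)
  writeLines(lines, path)
  invisible(path)
}

node_xyz <- function(tree) {
  as.matrix(tree$nodes[, c("x", "y", "z")])
}

edge_table <- function(tree) {
  n <- tree$nodes
  child <- which(n$parent != -1)
  parent_idx <- match(n$parent[child], n$id)
  list(child = child, parent = parent_idx)
}

#' Total dendritic length
#'
#' Sum over all parent-child segments of the Euclidean distance between
#' node coordinates (polyline convention; no radius weighting).
#'
#' @param tree A [neuron_tree()].
#' @return Length in micrometres.
#' @export
total_length <- function(tree) {
  e <- edge_table(tree)
  if (length(e$child) == 0) return(0)
  xyz <- node_xyz(tree)
  sum(sqrt(rowSums((xyz[e$child, , drop = FALSE] -
                    xyz[e$parent, , drop = FALSE])^2)))
}

#' Number of terminal points
#'
#' Non-root nodes with no children. A one-node tree has 0 terminals
#' (degenerate: the soma is never counted as a terminal).
#'
#' @param tree A [neuron_tree()].
#' @param types Optional integer vector of SWC type codes to restrict the
#'   count to (e.g. 3 for basal dendrites); default counts all neurites.
#' @return Integer count.
#' @export
terminal_points <- function(tree, types = NULL) {
  n <- tree$nodes
  has_child <- n$id %in% n$parent
  is_terminal <- !has_child & n$parent != -1
  if (!is.null(types)) is_terminal <- is_terminal & n$type %in% types
  sum(is_terminal)
}

#' Sholl intersection profile
#'
#' For each radius, counts the tree segments (parent-child edges) whose
#' endpoint distances from the soma straddle the radius (one endpoint
#' closer than r, the other at r or beyond); spheres are centered at the
#' soma. A segment is counted at most once per radius (endpoint-straddle
#' convention).
#'
#' @param tree A [neuron_tree()].
#' @param radii Strictly increasing positive radii (micrometres).
#' @return Integer vector of intersection counts, one per radius.
#' @export
sholl_profile <- function(tree, radii) {
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    abort("radii must be strictly increasing and > 0",
          class = "mmpscreen_invalid_input")
  }
  e <- edge_table(tree)
  if (length(e$child) == 0) return(rep(0L, length(radii)))
  xyz <- node_xyz(tree)
  soma <- xyz[match(tree$root, tree$nodes$id), ]
  d <- sqrt(rowSums((xyz - matrix(soma, nrow(xyz), 3, byrow = TRUE))^2))
  d_child <- d[e$child]
  d_parent <- d[e$parent]
  lo <- pmin(d_child, d_parent)
  hi <- pmax(d_child, d_parent)
  vapply(radii, function(r) sum(lo < r & r <= hi), integer(1))
}

#' All neurite metrics for one reconstruction
#'
#' @param tree A [neuron_tree()].
#' @param sholl_radii Optional radii for the Sholl profile; default: 10 um
#'   steps out to the tree's maximal extent.
#' @return List with `total_length`, `n_terminals`, `sholl_radii`,
#'   `sholl_counts`.
#' @export
neurite_metrics <- function(tree, sholl_radii = NULL) {
  if (is.null(sholl_radii)) {
    xyz <- node_xyz(tree)
    soma <- xyz[match(tree$root, tree$nodes$id), ]
    dmax <- max(sqrt(rowSums((xyz - matrix(soma, nrow(xyz), 3,
                                           byrow = TRUE))^2)))
    sholl_radii <- seq(10, max(10, ceiling(dmax / 10) * 10), by = 10)
  }
  list(total_length = total_length(tree),
       n_terminals = terminal_points(tree),
       sholl_radii = sholl_radii,
       sholl_counts = sholl_profile(tree, sholl_radii))
}
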