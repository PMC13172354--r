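#' Principal graph in embedding space
#'
#' A principal graph is the piecewise-linear skeleton fit through cells in a
#' 2-D embedding (typically by a trajectory-inference tool); here it is a
#' pipeline *input*: node coordinates plus an undirected edge list.
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y`.
#' @param edges Data frame with columns `from`, `to` (node ids).
#'
#' @return A `principal_graph` list with tibbles `nodes` and `edges`.
#' @export
#'
#' @examples
#' g <- principal_graph(
#'   nodes = data.frame(node_id = c("A", "B", "C"), x = c(0, 1, 2), y = 0),
#'   edges = data.frame(from = c("A", "B"), to = c("B", "C"))
#' )
#' extract_path(g, "A", "C")
principal_graph <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  nodes$node_id <- as.character(nodes$node_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$node_id)) {
    td_abort("duplicate node ids", "trajdyn_input_error")
  }
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    td_abort("node coordinates must be finite", "trajdyn_input_error")
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(unknown)) {
    td_abort(sprintf("edge endpoints not in node table: %s",
                     paste(unknown, collapse = ", ")), "trajdyn_input_error")
  }
  if (any(edges$from == edges$to)) {
    td_abort("self-loop edges are not allowed", "trajdyn_input_error")
  }
  structure(list(nodes = nodes, edges = edges), class = "principal_graph")
}

#' @export
print.principal_graph <- function(x, ...) {
  cat(sprintf("<principal_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

graph_to_igraph <- function(graph) {
  co <- graph$nodes
  w <- purrr::map2_dbl(graph$edges$from, graph$edges$to, function(a, b) {
    pa <- co[co$node_id == a, c("x", "y")]
    pb <- co[co$node_id == b, c("x", "y")]
    sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  })
  g <- igraph::graph_from_data_frame(
    cbind(graph$edges, weight = w), directed = FALSE,
    vertices = graph$nodes$node_id)
  g
}

#' Extract the geodesic node path between two graph nodes
#'
#' Returns the node-to-node path of minimum total Euclidean length through
#' the principal graph (edges weighted by the embedding-space length of each
#' segment). When several paths tie, the lexicographically smallest node
#' sequence is returned, so the result is deterministic.
#'
#' @param graph A [principal_graph()].
#' @param start,end Node ids.
#'
#' @return A `trajectory_path` list: `ordered_nodes` (character),
#'   `polyline` (n x 2 matrix of node coordinates in path order) and
#'   `arc_length` (total Euclidean length).
#' @export
extract_path <- function(graph, start, end) {
  stopifnot(inherits(graph, "principal_graph"))
  ids <- graph$nodes$node_id
  for (nd in c(start, end)) {
    if (!nd %in% ids) {
      td_abort(sprintf("node '%s' is not in the graph", nd), "trajdyn_input_error")
    }
  }
  if (start == end) {
    co <- graph$nodes[graph$nodes$node_id == start, ]
    return(new_trajectory_path(start, cbind(co$x, co$y)))
  }
  ig <- graph_to_igraph(graph)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = start, to = end, weights = NULL))
  if (length(sp$res) == 0L) {
    td_abort(sprintf("no path connects '%s' and '%s'", start, end),
             "trajdyn_path_error")
  }
  seqs <- purrr::map(sp$res, ~ names(.x))
  # deterministic tie-break: lexicographically smallest node sequence
  keys <- purrr::map_chr(seqs, ~ paste(.x, collapse = "\r"))
  nodes <- seqs[[order(keys)[1]]]
  co <- graph$nodes[match(nodes, graph$nodes$node_id), ]
  new_trajectory_path(nodes, cbind(co$x, co$y))
}

new_trajectory_path <- function(nodes, polyline) {
  polyline <- unname(as.matrix(polyline))
  seg <- if (nrow(polyline) > 1) {
    sqrt(rowSums((polyline[-1, , drop = FALSE] -
                  polyline[-nrow(polyline), , drop = FALSE])^2))
  } else numeric(0)
  structure(list(ordered_nodes = nodes, polyline = polyline,
                 arc_length = sum(seg), segment_lengths = seg),
            class = "trajectory_path")
}

#' @export
print.trajectory_path <- function(x, ...) {
  cat(sprintf("<trajectory_path> %d nodes (%s -> %s), arc length %.4g\n",
              length(x$ordered_nodes), x$ordered_nodes[1],
              x$ordered_nodes[length(x$ordered_nodes)], x$arc_length))
  invisible(x)
}

#' Euclidean distance from points to a trajectory path
#'
#' The distance from each point to the path polyline, treating every edge as
#' a closed segment: the orthogonal projection onto the segment's supporting
#' line, clamped to its endpoints. A single-node path degenerates to plain
#' point-to-point distance. With `mode = "node"` distances are measured to
#' the node set only (a sensitivity-analysis variant).
#'
#' @param points Numeric matrix or data frame of 2-D coordinates (columns
#'   x, y), one row per point.
#' @param path A `trajectory_path`.
#' @param mode `"segment"` (default) or `"node"`.
#'
#' @return Numeric vector of nonnegative distances, one per point row.
#' @export
distance_to_path <- function(points, path, mode = c("segment", "node")) {
  mode <- match.arg(mode)
  stopifnot(inherits(path, "trajectory_path"))
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) td_abort("`points` must have two columns", "trajdyn_input_error")
  storage.mode(pts) <- "double"
  poly <- path$polyline
  n_seg <- nrow(poly) - 1L
  if (n_seg < 1L || mode == "node") {
    d2 <- outer(pts[, 1], poly[, 1], "-")^2 + outer(pts[, 2], poly[, 2], "-")^2
    return(sqrt(apply(d2, 1, min)))
  }
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n_seg)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Select cells near a trajectory path by a distance percentile
#'
#' Computes every cell's Euclidean distance to the path polyline, sets the
#' threshold at the given percentile of the full distance vector (linear
#' interpolation between order statistics, the type-7 convention), and
#' selects the cells whose distance is less than or equal to the threshold.
#'
#' @param embedding Data frame with columns `cell_id`, `x`, `y`, or a matrix
#'   with cell row names.
#' @param path A `trajectory_path`.
#' @param percentile Fraction in (0, 1\]; default 0.20 (the 20th percentile).
#' @param mode Distance mode passed to [distance_to_path()].
#'
#' @return A `cell_selection` list: `cells` (tibble `cell_id`, `distance`,
#'   `selected`), `threshold`, `percentile`.
#' @export
select_cells_near_path <- function(embedding, path, percentile = 0.20,
                                   mode = c("segment", "node")) {
  mode <- match.arg(mode)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      !is.finite(percentile) || percentile <= 0 || percentile > 1) {
    td_abort("`percentile` must lie in (0, 1]", "trajdyn_input_error")
  }
  emb <- normalize_embedding(embedding)
  if (nrow(emb) < 5L) {
    td_abort("need at least 5 cells to set a distance percentile",
             "trajdyn_input_error")
  }
  d <- distance_to_path(cbind(emb$x, emb$y), path, mode = mode)
  thr <- unname(quantile(d, probs = percentile, type = 7))
  cells <- tibble(cell_id = emb$cell_id, distance = d, selected = d <= thr)
  structure(list(cells = cells, threshold = thr, percentile = percentile,
                 path = path),
            class = "cell_selection")
}

normalize_embedding <- function(embedding) {
  if (is.matrix(embedding)) {
    if (is.null(rownames(embedding))) {
      td_abort("embedding matrix needs cell row names", "trajdyn_input_error")
    }
    return(tibble(cell_id = rownames(embedding),
                  x = embedding[, 1], y = embedding[, 2]))
  }
  emb <- as_tibble(embedding)
  stopifnot(all(c("cell_id", "x", "y") %in% names(emb)))
  emb$cell_id <- as.character(emb$cell_id)
  emb
}

#' @export
print.cell_selection <- function(x, ...) {
  cat(sprintf("<cell_selection> %d / %d cells within %.4g (%.0fth percentile)\n",
              sum(x$cells$selected), nrow(x$cells), x$threshold,
              100 * x$percentile))
  invisible(x)
}

selected_ids <- function(selection) {
  stopifnot(inherits(selection, "cell_selection"))
  selection$cells$cell_id[selection$cells$selected]
}
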