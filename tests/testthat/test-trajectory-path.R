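toy_graph <- function() {
  principal_graph(
    nodes = data.frame(node_id = c("A", "B", "C", "D", "E"),
                       x = c(0, 1, 2, 3, 1.5), y = c(0, 0, 0, 0, 1)),
    edges = data.frame(from = c("A", "B", "C", "A", "E"),
                       to = c("B", "C", "D", "E", "D")))
}

test_that("extract_path returns the minimum-length route deterministically", {
  g <- toy_graph()
  # direct chain A-B-C-D has length 3; A-E-D has length 2*sqrt(1.5^2+1) = 3.6
  p <- extract_path(g, "A", "D")
  expect_equal(p$ordered_nodes, c("A", "B", "C", "D"))
  expect_equal(p$arc_length, 3)

  # single-node path degenerates cleanly
  p0 <- extract_path(g, "B", "B")
  expect_equal(p0$ordered_nodes, "B")
  expect_equal(p0$arc_length, 0)

  # unique path on a chain
  chain <- principal_graph(
    data.frame(node_id = c("A", "B", "C"), x = 0:2, y = 0),
    data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(extract_path(chain, "A", "C")$ordered_nodes, c("A", "B", "C"))

  expect_error(extract_path(g, "A", "Z"), class = "trajdyn_input_error")
  disconnected <- principal_graph(
    data.frame(node_id = c("A", "B", "C", "D"), x = c(0, 1, 5, 6), y = 0),
    data.frame(from = c("A", "C"), to = c("B", "D")))
  expect_error(extract_path(disconnected, "A", "D"), "no path",
               class = "trajdyn_path_error")
})

test_that("extract_path agrees with exhaustive enumeration on random graphs", {
  for (seed in 1:100) {
    n <- sample(4:10, 1)
    rg <- random_geometric_graph(n, seed)
    g <- principal_graph(rg$nodes, rg$edges)
    ends <- sample(rg$nodes$node_id, 2)
    oracle <- oracle_shortest_simple_path(rg$nodes, rg$edges,
                                          ends[1], ends[2])
    if (!is.finite(oracle$len)) {
      expect_error(extract_path(g, ends[1], ends[2]),
                   class = "trajdyn_path_error")
      next
    }
    p <- extract_path(g, ends[1], ends[2])
    expect_equal(p$arc_length, oracle$len, tolerance = 1e-9)
    # deterministic tie-break: the lexicographically smallest optimal route
    keys <- vapply(oracle$paths, paste, character(1), collapse = "\r")
    expect_equal(p$ordered_nodes, oracle$paths[[order(keys)[1]]])
  }
})

test_that("distance_to_path projects onto closed segments", {
  path <- extract_path(toy_graph(), "A", "D")
  # point on a segment interior
  expect_equal(distance_to_path(cbind(1.5, 0), path), 0)
  # orthogonal projection
  seg <- new_path_for_test(rbind(c(0, 0), c(2, 0)))
  expect_equal(distance_to_path(cbind(0, 1), seg), 1)
  # beyond an endpoint the distance clamps to the endpoint
  expect_equal(distance_to_path(cbind(-3, 4), seg), 5)
  # single-node path degenerates to point distance
  single <- extract_path(toy_graph(), "E", "E")
  expect_equal(distance_to_path(cbind(1.5, 3), single), 2)
})

test_that("distance_to_path matches a dense-sampling oracle", {
  set.seed(21)
  poly <- cbind(cumsum(runif(5, 0.5, 2)), rnorm(5))
  path <- new_path_for_test(poly)
  pts <- cbind(runif(5, -1, 8), runif(5, -3, 3))
  for (i in seq_len(nrow(pts))) {
    expect_equal(distance_to_path(pts[i, , drop = FALSE], path),
                 oracle_polyline_distance(pts[i, ], poly),
                 tolerance = 1e-3)
  }
})

test_that("distance_to_path is invariant under rigid motions", {
  set.seed(33)
  poly <- cbind(runif(6), runif(6))
  pts <- cbind(runif(20, -1, 2), runif(20, -1, 2))
  d0 <- distance_to_path(pts, new_path_for_test(poly))
  for (theta in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    shift <- c(5, -3)
    d1 <- distance_to_path(sweep(pts %*% R, 2, shift, "+"),
                           new_path_for_test(sweep(poly %*% R, 2, shift, "+")))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("percentile selection interpolates and is monotone in percentile", {
  emb <- tibble::tibble(cell_id = sprintf("c%02d", 1:10),
                        x = 1:10, y = 1:10)
  # vertical segment at x = 0..; craft distances exactly 1..10
  path <- new_path_for_test(rbind(c(0, 0), c(0, 100)))
  emb$x <- 1:10; emb$y <- seq(5, 50, by = 5)
  sel <- select_cells_near_path(emb, path, percentile = 0.20)
  expect_equal(sel$threshold, 2.8)   # type-7 interpolation of 1..10 at 0.2
  expect_equal(sum(sel$cells$selected), 2)
  expect_setequal(selected_ids(sel), c("c01", "c02"))

  # all cells on the polyline: threshold 0, everyone selected
  on_path <- tibble::tibble(cell_id = sprintf("p%d", 1:6), x = 0,
                            y = seq(10, 60, by = 10))
  sel0 <- select_cells_near_path(on_path, path, percentile = 0.20)
  expect_equal(sel0$threshold, 0)
  expect_true(all(sel0$cells$selected))

  # full percentile selects everything; counts are monotone in percentile
  counts <- vapply(c(0.1, 0.2, 0.5, 0.8, 1),
                   function(p) sum(select_cells_near_path(emb, path,
                                                          p)$cells$selected),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[5], 10)
  expect_error(select_cells_near_path(emb, path, percentile = 0),
               class = "trajdyn_input_error")
  expect_error(select_cells_near_path(emb, path, percentile = 1.5),
               class = "trajdyn_input_error")
})
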