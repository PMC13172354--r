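# Independent oracles used to cross-check the implementation. Each is coded
# from the mathematical definition, not from the package internals.

# Tricube-weighted local polynomial regression, Cleveland's definition:
# bandwidth = distance to the floor(n * span)-th nearest neighbor.
oracle_loess <- function(x, y, span = 0.3, degree = 2, x0 = x) {
  n <- length(x)
  q <- min(n, floor(n * span + 1e-9))
  sapply(x0, function(p) {
    d <- abs(x - p)
    dq <- sort(d)[q]
    w <- rep(0, n)
    if (dq > 0) {
      u <- d / dq
      w[u < 1] <- (1 - u[u < 1]^3)^3
    } else {
      w[d == 0] <- 1
    }
    keep <- w > 0
    X <- outer(x[keep] - p, 0:degree, "^")
    fit <- lm.wfit(X, y[keep], w[keep])
    unname(fit$coefficients[1])
  })
}

# Spearman rho as the Pearson correlation of mid-ranks, written out in full.
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Minimum distance from a point to a polyline by dense sampling of each
# segment.
oracle_polyline_distance <- function(point, polyline, samples_per_segment = 1e5) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1)) {
    t <- seq(0, 1, length.out = samples_per_segment)
    px <- polyline[i, 1] + t * (polyline[i + 1, 1] - polyline[i, 1])
    py <- polyline[i, 2] + t * (polyline[i + 1, 2] - polyline[i, 2])
    best <- min(best, sqrt(min((px - point[1])^2 + (py - point[2])^2)))
  }
  best
}

# All simple paths between two nodes by depth-first enumeration; returns the
# minimum total Euclidean length and the node sequences achieving it.
oracle_shortest_simple_path <- function(nodes, edges, start, end) {
  adj <- lapply(setNames(nodes$node_id, nodes$node_id), function(id) {
    c(edges$to[edges$from == id], edges$from[edges$to == id])
  })
  coord <- function(id) {
    i <- match(id, nodes$node_id)
    c(nodes$x[i], nodes$y[i])
  }
  seglen <- function(a, b) sqrt(sum((coord(a) - coord(b))^2))
  best <- list(len = Inf, paths = list())
  walk <- function(path, len) {
    cur <- path[length(path)]
    if (cur == end) {
      if (len < best$len - 1e-12) {
        best$len <<- len
        best$paths <<- list(path)
      } else if (abs(len - best$len) <= 1e-12) {
        best$paths <<- c(best$paths, list(path))
      }
      return(invisible())
    }
    for (nb in adj[[cur]]) {
      if (!nb %in% path) walk(c(path, nb), len + seglen(cur, nb))
    }
  }
  walk(start, 0)
  best
}

# Naive 2-D discrete Fourier transform magnitude straight from the
# definition, one frequency at a time (zero frequency at element [1, 1],
# matching stats::fft ordering).
oracle_dft_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  iidx <- matrix(0:(nr - 1), nr, nc)
  jidx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  out <- matrix(0, nr, nc)
  for (u in 0:(nr - 1)) {
    for (v in 0:(nc - 1)) {
      out[u + 1, v + 1] <-
        Mod(sum(img * exp(-2i * pi * (u * iidx / nr + v * jidx / nc))))
    }
  }
  out
}

# Build a trajectory_path directly from a polyline matrix.
new_path_for_test <- function(poly) {
  trajdyn:::new_trajectory_path(sprintf("n%d", seq_len(nrow(poly))), poly)
}

selected_ids <- function(sel) sel$cells$cell_id[sel$cells$selected]

# Small random geometric graph for path-extraction tests.
random_geometric_graph <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- tibble::tibble(node_id = sprintf("N%02d", seq_len(n_nodes)),
                          x = runif(n_nodes, 0, 10),
                          y = runif(n_nodes, 0, 10))
  # random connected graph: spanning tree plus extra edges
  perm <- sample(n_nodes)
  from <- integer(0); to <- integer(0)
  for (k in 2:n_nodes) {
    from <- c(from, perm[sample(k - 1, 1)]); to <- c(to, perm[k])
  }
  extra <- max(1L, n_nodes %/% 2L)
  for (k in seq_len(extra)) {
    pair <- sample(n_nodes, 2)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  edges <- tibble::tibble(from = nodes$node_id[from], to = nodes$node_id[to])
  edges <- edges[edges$from != edges$to, ]
  dedup <- !duplicated(paste(pmin(edges$from, edges$to),
                             pmax(edges$from, edges$to)))
  list(nodes = nodes, edges = edges[dedup, ])
}

# Toy raw-count matrix with prescribed per-cell feature counts; total genes
# padded so the largest feature count fits.
toy_count_matrix <- function(feature_counts, n_genes = max(feature_counts) + 10,
                             mito_counts = rep(0, length(feature_counts)),
                             n_mito_genes = 5) {
  n_cells <- length(feature_counts)
  genes <- c(sprintf("MT-%d", seq_len(n_mito_genes)),
             sprintf("G%05d", seq_len(n_genes - n_mito_genes)))
  m <- matrix(0, n_cells, n_genes,
              dimnames = list(sprintf("cell%d", seq_len(n_cells)), genes))
  for (i in seq_len(n_cells)) {
    k <- feature_counts[i] - (mito_counts[i] > 0)
    m[i, n_mito_genes + seq_len(k)] <- 1
    if (mito_counts[i] > 0) m[i, 1] <- mito_counts[i]
  }
  expression_matrix(m, "raw_counts")
}
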