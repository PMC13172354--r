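#' Configuration for a synthetic trajectory dataset
#'
#' Describes a simulated single-cell dataset laid out along a 2-D
#' differentiation trajectory: a piecewise-linear principal graph, cells
#' scattered around it with monotone pseudotime along its arc length, and a
#' log-normalized expression matrix in which a known subset of genes varies
#' smoothly with pseudotime (the ground truth for recovery tests).
#'
#' Dynamic mean curves are logistic in normalized pseudotime for the
#' monotone profiles and a Gaussian bump at mid-path for the transient
#' profile; static genes have a constant mean. Gaussian noise is added and
#' the result truncated at zero (mimicking log-normalized nonnegativity),
#' then dropout zeroes each entry independently.
#'
#' @param n_cells,n_genes Positive counts.
#' @param frac_dynamic Fraction of genes given a dynamic profile, in \[0, 1\].
#' @param dynamic_profiles Profiles cycled over the dynamic genes; subset of
#'   `"monotone_up"`, `"monotone_down"`, `"transient"`.
#' @param amplitude Peak-to-baseline height of the dynamic mean curves
#'   (log-normalized expression units).
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param dropout_rate Probability that any entry is set to 0, in \[0, 1\].
#' @param n_branch_nodes Number of principal-graph nodes along the main
#'   path (>= 2).
#' @param baseline Constant mean of static genes (and the floor of dynamic
#'   curves).
#' @param jitter_sd Standard deviation of the isotropic Gaussian jitter of
#'   cell embeddings around the path; jitter is capped at `3 * jitter_sd`
#'   so every cell lies within that radius of the generating polyline.
#' @param side_branch Add a short side branch to the graph (cells stay on
#'   the main path; the branch only complicates routing).
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   dataset bit for bit.
#'
#' @return A `trajectory_sim_config` list.
#' @export
trajectory_sim_config <- function(n_cells = 500, n_genes = 500,
                                  frac_dynamic = 0.1,
                                  dynamic_profiles = c("monotone_up",
                                                       "monotone_down",
                                                       "transient"),
                                  amplitude = 2, noise_sd = 0.3,
                                  dropout_rate = 0.2, n_branch_nodes = 20,
                                  baseline = 1, jitter_sd = 0.3,
                                  side_branch = FALSE, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1 || n_cells != round(n_cells)) {
    td_abort("`n_cells` must be a positive integer", "trajdyn_config_error")
  }
  if (!is.numeric(n_genes) || n_genes < 1 || n_genes != round(n_genes)) {
    td_abort("`n_genes` must be a positive integer", "trajdyn_config_error")
  }
  td_assert_scalar_number(frac_dynamic, "frac_dynamic", 0, 1)
  dynamic_profiles <- match.arg(dynamic_profiles,
                                c("monotone_up", "monotone_down", "transient"),
                                several.ok = TRUE)
  td_assert_scalar_number(amplitude, "amplitude", lower = 0)
  td_assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  td_assert_scalar_number(dropout_rate, "dropout_rate", 0, 1)
  if (!is.numeric(n_branch_nodes) || n_branch_nodes < 2) {
    td_abort("`n_branch_nodes` must be an integer >= 2", "trajdyn_config_error")
  }
  td_assert_scalar_number(baseline, "baseline", lower = 0)
  td_assert_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 frac_dynamic = frac_dynamic,
                 dynamic_profiles = dynamic_profiles,
                 amplitude = amplitude, noise_sd = noise_sd,
                 dropout_rate = dropout_rate,
                 n_branch_nodes = as.integer(n_branch_nodes),
                 baseline = baseline, jitter_sd = jitter_sd,
                 side_branch = isTRUE(side_branch), seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

# logistic rise over t in [0,1]; steepness 10 keeps it strictly monotone
# yet near its asymptotes at the path ends
profile_mean <- function(profile, t, amplitude, baseline) {
  switch(profile,
    monotone_up   = baseline + amplitude / (1 + exp(-10 * (t - 0.5))),
    monotone_down = baseline + amplitude / (1 + exp(10 * (t - 0.5))),
    transient     = baseline + amplitude * exp(-(t - 0.5)^2 / (2 * 0.12^2)),
    static        = rep(baseline, length(t))
  )
}

#' Generate a synthetic trajectory dataset with known gene dynamics
#'
#' Draws cells uniformly along the arc length of a curved principal path,
#' sets pseudotime to the arc-length position, jitters the embedding with
#' capped isotropic Gaussian noise, and simulates log-normalized expression
#' with the configured mix of dynamic and static genes. All randomness flows
#' from `config$seed` through one generator stream, in the order: cell
#' positions, embedding jitter, expression noise, dropout mask.
#'
#' @param config A [trajectory_sim_config()].
#'
#' @return A `trajectory_dataset` list: `expression` (cells x genes
#'   `expression_matrix`, log-normalized), `embedding` (tibble `cell_id`,
#'   `x`, `y`), `pseudotime` (tibble `cell_id`, `pseudotime`), `graph`
#'   (a [principal_graph()]), `truth` (tibble `gene_id`, `truth` in
#'   `dynamic_up`, `dynamic_down`, `dynamic_transient`, `static`), and the
#'   `config`.
#' @export
#'
#' @examples
#' ds <- generate_trajectory_dataset(
#'   trajectory_sim_config(n_cells = 50, n_genes = 20, seed = 1))
#' table(ds$truth$truth)
generate_trajectory_dataset <- function(config = trajectory_sim_config()) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  set.seed(config$seed)

  # --- principal graph: a gentle arc, nodes evenly spaced in parameter ---
  m <- config$n_branch_nodes
  u <- seq(0, 1, length.out = m)
  nodes <- tibble(node_id = sprintf("Y_%d", seq_len(m)),
                  x = 10 * u, y = 2 * sin(pi * u))
  edges <- tibble(from = nodes$node_id[-m], to = nodes$node_id[-1])
  if (config$side_branch) {
    k <- max(2L, m %/% 2L)
    bx <- nodes$x[k]; by <- nodes$y[k]
    br <- tibble(node_id = c("B_1", "B_2"),
                 x = bx + c(0.8, 1.6), y = by + c(1.2, 2.4))
    nodes <- dplyr::bind_rows(nodes, br)
    edges <- dplyr::bind_rows(edges,
                              tibble(from = c(nodes$node_id[k], "B_1"),
                                     to = c("B_1", "B_2")))
  }
  graph <- principal_graph(nodes, edges)
  main_path <- new_trajectory_path(
    nodes$node_id[seq_len(m)],
    cbind(nodes$x[seq_len(m)], nodes$y[seq_len(m)]))

  # --- cells along the arc length ---
  n <- config$n_cells
  s <- sort(runif(n, 0, main_path$arc_length))
  base_pts <- polyline_point_at(main_path, s)
  jit <- matrix(rnorm(2 * n, sd = config$jitter_sd), ncol = 2)
  if (config$jitter_sd > 0) {
    r <- sqrt(rowSums(jit^2))
    cap <- 3 * config$jitter_sd
    over <- r > cap
    jit[over, ] <- jit[over, , drop = FALSE] * (cap / r[over])
  }
  cell_id <- sprintf("cell_%04d", seq_len(n))
  embedding <- tibble(cell_id = cell_id,
                      x = base_pts[, 1] + jit[, 1],
                      y = base_pts[, 2] + jit[, 2])
  pseudotime <- tibble(cell_id = cell_id, pseudotime = s)

  # --- gene truth assignment ---
  g <- config$n_genes
  n_dyn <- round(config$frac_dynamic * g)
  profiles <- if (n_dyn > 0) {
    rep(config$dynamic_profiles, length.out = n_dyn)
  } else character(0)
  truth_label <- c(c(monotone_up = "dynamic_up", monotone_down = "dynamic_down",
                     transient = "dynamic_transient")[profiles],
                   rep("static", g - n_dyn))
  gene_id <- sprintf("gene_%04d", seq_len(g))
  truth <- tibble(gene_id = gene_id, truth = unname(truth_label))

  # --- expression: mean curve + truncated noise + dropout ---
  t_norm <- s / main_path$arc_length
  means <- vapply(seq_len(g), function(j) {
    prof <- if (j <= n_dyn) profiles[j] else "static"
    profile_mean(prof, t_norm, config$amplitude, config$baseline)
  }, numeric(n))
  expr <- means
  if (config$noise_sd > 0) {
    expr <- expr + matrix(rnorm(n * g, sd = config$noise_sd), n, g)
  }
  expr <- pmax(expr, 0)
  if (config$dropout_rate > 0) {
    drop_mask <- matrix(runif(n * g) < config$dropout_rate, n, g)
    expr[drop_mask] <- 0
  }
  dimnames(expr) <- list(cell_id, gene_id)

  structure(list(expression = expression_matrix(expr, "log_normalized"),
                 embedding = embedding, pseudotime = pseudotime,
                 graph = graph, truth = truth, path = main_path,
                 config = config),
            class = "trajectory_dataset")
}

# point on the polyline at arc-length positions s (vectorized)
polyline_point_at <- function(path, s) {
  poly <- path$polyline
  seg <- path$segment_lengths
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), path$arc_length)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- ifelse(seg[idx] > 0, (s - cum[idx]) / seg[idx], 0)
  poly[idx, , drop = FALSE] +
    (poly[idx + 1L, , drop = FALSE] - poly[idx, , drop = FALSE]) * frac
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(paste0("<trajectory_dataset> %d cells x %d genes, ",
                     "%d dynamic-truth genes, %d graph nodes\n"),
              x$config$n_cells, x$config$n_genes,
              sum(x$truth$truth != "static"), nrow(x$graph$nodes)))
  invisible(x)
}
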