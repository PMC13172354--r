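sim_small <- function(...) {
  generate_trajectory_dataset(trajectory_sim_config(...))
}

test_that("detection prefilter applies the at-least-10% rule inclusively", {
  n <- 100
  cells <- sprintf("c%03d", 1:n)
  m <- matrix(0, n, 3, dimnames = list(cells, c("g10", "g09", "g00")))
  m[1:10, "g10"] <- 1    # detected in exactly 10% of cells
  m[1:9, "g09"] <- 1     # detected in 9%
  mat <- expression_matrix(m, "log_normalized")
  pre <- prefilter_genes(mat, cells, dynamics_config())
  expect_equal(pre$passed_prefilter[pre$gene_id == "g10"], TRUE)
  expect_equal(pre$passed_prefilter[pre$gene_id == "g09"], FALSE)
  expect_equal(pre$detection_rate, c(0.10, 0.09, 0))

  # zero threshold keeps everything
  all_in <- prefilter_genes(mat, cells,
                            dynamics_config(detection_min_fraction = 0))
  expect_true(all(all_in$passed_prefilter))
  expect_error(prefilter_genes(mat, character(0)),
               class = "trajdyn_input_error")
})

test_that("fit_loess reproduces polynomials and matches the tricube oracle", {
  set.seed(5)
  t <- sort(runif(60))
  # a global quadratic is reproduced exactly by degree-2 local fits
  y_quad <- 1 + 2 * t - 3 * t^2
  expect_equal(fit_loess(t, y_quad, span = 0.75, degree = 2), y_quad,
               tolerance = 1e-6)
  # constant input returns the constant
  expect_equal(fit_loess(t, rep(2.5, 60)), rep(2.5, 60), tolerance = 1e-9)

  # noisy logistic at the pipeline settings vs the independent oracle
  y <- 2 / (1 + exp(-10 * (t - 0.5))) + rnorm(60, sd = 0.3)
  expect_equal(fit_loess(t, y, span = 0.3, degree = 2),
               oracle_loess(t, y, span = 0.3, degree = 2),
               tolerance = 1e-8)
  # degree 1 variant
  expect_equal(fit_loess(t, y, span = 0.5, degree = 1),
               oracle_loess(t, y, span = 0.5, degree = 1),
               tolerance = 1e-8)

  expect_error(fit_loess(t[1:5], y[1:5]), class = "trajdyn_input_error")
  expect_error(fit_loess(rep(1, 20), rnorm(20)), class = "trajdyn_input_error")
})

test_that("dynamics_range reproduces the spread-ratio definition", {
  expect_equal(dynamics_range(0:4, c(0.5, 1, 2, 3, 3.5)), 0.75)
  y <- c(0.3, 1.7, 0.9, 2.2)
  expect_equal(dynamics_range(y, y), 1)          # perfect fit
  expect_equal(dynamics_range(y, rep(1, 4)), 0)  # flat fit
  expect_true(is.na(dynamics_range(rep(2, 5), 1:5)))  # degenerate spread
  expect_error(dynamics_range(1:4, 1:5), class = "trajdyn_input_error")

  # invariances: shared shift, shared positive rescale
  yh <- c(0.5, 1, 2, 3, 3.5)
  expect_equal(dynamics_range(0:4 + 7, yh + 7), 0.75)
  expect_equal(dynamics_range((0:4) * 3.2, yh * 3.2), 0.75)
})

test_that("classification applies the strict below-cutoff rule per branch", {
  rec <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        dynamics_range = c(0.049, 0.05, 0.099, NA))
  out <- classify_dynamics(rec, static_cutoff = 0.05)
  expect_equal(out$dynamics_class, c("static", "dynamic", "dynamic",
                                     "degenerate"))
  # fibroblast-branch preset cutoff 0.1
  fib <- classify_dynamics(rec, dynamics_config("fibroblast")$static_cutoff)
  expect_equal(fib$dynamics_class, c("static", "static", "static",
                                     "degenerate"))
})

test_that("spearman_rank matches the mid-rank oracle and handles ties", {
  expect_equal(spearman_rank(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rank(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_rank(1:5, rep(2, 5)), list(rho = 0, p_value = 1))

  # exhaustive small inputs from a fixed grid, with ties
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    x <- sample(c(1, 1, 2, 3, 3, 4, 5), n, replace = TRUE)
    if (diff(range(x)) == 0) x[1] <- x[1] + 1
    y <- sample(c(0, 0, 1, 2, 2, 3), n, replace = TRUE)
    if (diff(range(y)) == 0) next
    got <- spearman_rank(x, y)
    expect_equal(got$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    # cross-check against the standard implementation
    expect_equal(got$rho,
                 suppressWarnings(unname(stats::cor.test(x, y,
                   method = "spearman")$estimate)),
                 tolerance = 1e-12)
    if (abs(got$rho) < 1) {
      expect_equal(got$p_value,
                   suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                                    exact = FALSE)$p.value),
                   tolerance = 1e-10)
    }
  }
  expect_error(spearman_rank(1:2, 1:2), class = "trajdyn_input_error")
  expect_error(spearman_rank(rep(1, 5), 1:5), class = "trajdyn_input_error")
})

test_that("fate ranking applies Bonferroni, strict cutoff and tie rules", {
  rec <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:6),
    dynamics_class = c("dynamic", "dynamic", "dynamic", "dynamic",
                       "static", "degenerate"),
    rho = c(0.71, 0.70, -0.9, 0.71, 0.99, NA),
    p_value = c(0.001, 0.002, 1e-6, 0.0005, 1e-9, NA))
  out <- rank_fate_genes(rec, dynamics_config(top_k = 2))
  # Bonferroni over the 4 dynamic genes only
  expect_equal(out$p_adjusted[1], 0.004)
  expect_true(is.na(out$p_adjusted[5]))
  # strict |rho| > 0.7
  expect_equal(out$high_rho, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  # ranking: ties on |rho| = 0.71 broken by smaller p
  up <- out[!is.na(out$direction) & out$direction == "up", ]
  expect_equal(up$gene_id[order(up$rank_in_direction)][1:2], c("g04", "g01"))
  # static gene never ranked despite its large rho
  expect_true(is.na(out$rank_in_direction[5]))
  # multiply-and-cap: p 0.001 over 40 dynamic genes -> 0.04
  many <- tibble::tibble(gene_id = sprintf("h%02d", 1:40),
                         dynamics_class = "dynamic",
                         rho = seq(0.1, 0.9, length.out = 40),
                         p_value = rep(0.001, 40))
  adj <- rank_fate_genes(many, dynamics_config())$p_adjusted
  expect_equal(adj, rep(0.04, 40))
  expect_true(all(adj >= many$p_value) && all(adj <= 1))
})

test_that("pipeline recovers ground truth and is order-invariant", {
  ds <- sim_small(n_cells = 300, n_genes = 120, frac_dynamic = 0.25,
                  dynamic_profiles = c("monotone_up", "monotone_down"),
                  amplitude = 2, noise_sd = 0.3, dropout_rate = 0.2, seed = 2)
  path <- ds$path
  sel <- select_cells_near_path(ds$embedding, path, 0.2)
  res <- run_dynamics_pipeline(ds$expression, sel, ds$pseudotime,
                               dynamics_config("pericyte"))
  tr <- dplyr::left_join(tidy(res), ds$truth, by = "gene_id")
  mono <- tr[tr$truth %in% c("dynamic_up", "dynamic_down"), ]
  expect_gte(mean(mono$dynamics_class == "dynamic", na.rm = TRUE), 0.9)
  signs <- sign(mono$rho[mono$dynamics_class == "dynamic"])
  want <- ifelse(mono$truth[mono$dynamics_class == "dynamic"] == "dynamic_up",
                 1, -1)
  expect_equal(signs, want)

  # gene order never changes the per-gene results
  shuffled <- expression_matrix(
    as.matrix(expr_values(ds$expression))[, sample(ncol(ds$expression))],
    "log_normalized")
  res2 <- run_dynamics_pipeline(shuffled, sel, ds$pseudotime,
                                dynamics_config("pericyte"))
  a <- dplyr::arrange(tidy(res), gene_id)
  b <- dplyr::arrange(tidy(res2), gene_id)
  expect_equal(a, b)
})

test_that("pipeline with no dynamic genes yields empty fate lists", {
  ds <- sim_small(n_cells = 200, n_genes = 40, frac_dynamic = 0,
                  noise_sd = 0.05, baseline = 1, dropout_rate = 0, seed = 6)
  sel <- select_cells_near_path(ds$embedding, ds$path, 0.2)
  res <- run_dynamics_pipeline(ds$expression, sel, ds$pseudotime,
                               dynamics_config("pericyte"))
  expect_equal(length(res$high_rho), 0)
  expect_true(all(abs(tidy(res)$rho) < 0.7, na.rm = TRUE))
})
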