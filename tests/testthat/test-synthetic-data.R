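test_that("dynamic gene count, determinism and truth partition are exact", {
  cfg <- trajectory_sim_config(n_cells = 500, n_genes = 500,
                               frac_dynamic = 0.1, seed = 1)
  ds <- generate_trajectory_dataset(cfg)
  expect_equal(sum(ds$truth$truth != "static"), 50)
  expect_setequal(unique(ds$truth$truth),
                  c("dynamic_up", "dynamic_down", "dynamic_transient", "static"))
  expect_equal(nrow(ds$truth), 500)

  ds2 <- generate_trajectory_dataset(cfg)
  expect_identical(as.matrix(expr_values(ds$expression)),
                   as.matrix(expr_values(ds2$expression)))
  expect_identical(ds$embedding, ds2$embedding)
  expect_identical(ds$pseudotime, ds2$pseudotime)
})

test_that("zero-noise monotone genes follow their mean curve exactly", {
  ds <- generate_trajectory_dataset(trajectory_sim_config(
    n_cells = 80, n_genes = 10, frac_dynamic = 0.4,
    dynamic_profiles = c("monotone_up", "monotone_down"),
    noise_sd = 0, dropout_rate = 0, seed = 3))
  v <- as.matrix(expr_values(ds$expression))
  ord <- order(ds$pseudotime$pseudotime)
  up <- ds$truth$gene_id[ds$truth$truth == "dynamic_up"]
  dn <- ds$truth$gene_id[ds$truth$truth == "dynamic_down"]
  for (g in up) expect_true(all(diff(v[ord, g]) > 0))
  for (g in dn) expect_true(all(diff(v[ord, g]) < 0))
  # perfect concordance with pseudotime
  expect_equal(spearman_rank(ds$pseudotime$pseudotime, v[, up[1]])$rho, 1)
  expect_equal(spearman_rank(ds$pseudotime$pseudotime, v[, dn[1]])$rho, -1)
})

test_that("pseudotime tracks arc length and embeddings stay near the path", {
  cfg <- trajectory_sim_config(n_cells = 300, n_genes = 5, jitter_sd = 0.25,
                               seed = 9)
  ds <- generate_trajectory_dataset(cfg)
  # pseudotime is the arc-length position itself: nondecreasing along the path
  expect_true(all(ds$pseudotime$pseudotime >= 0))
  expect_lte(max(ds$pseudotime$pseudotime), ds$path$arc_length)
  d <- distance_to_path(cbind(ds$embedding$x, ds$embedding$y), ds$path)
  expect_true(all(d <= 3 * cfg$jitter_sd + 1e-9))
})

test_that("empirical dropout fraction matches the configured rate", {
  cfg <- trajectory_sim_config(n_cells = 400, n_genes = 400, frac_dynamic = 0,
                               noise_sd = 0, dropout_rate = 0.3,
                               baseline = 5, seed = 4)
  ds <- generate_trajectory_dataset(cfg)
  v <- as.matrix(expr_values(ds$expression))
  p_hat <- mean(v == 0)
  se <- sqrt(0.3 * 0.7 / length(v))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(trajectory_sim_config(n_cells = 0), class = "trajdyn_config_error")
  expect_error(trajectory_sim_config(frac_dynamic = 1.2),
               class = "trajdyn_config_error")
  expect_error(trajectory_sim_config(noise_sd = -1),
               class = "trajdyn_config_error")
  expect_error(trajectory_sim_config(n_branch_nodes = 1),
               class = "trajdyn_config_error")
})

test_that("fiber image generator honours construction, isotropy and seed", {
  img <- generate_fiber_image(64, 48, angle = 0, coherence = 1, seed = 1)
  expect_equal(dim(img), c(48, 64))
  # horizontal fibers: every row is constant along x
  expect_equal(apply(img, 1, function(r) diff(range(r))), rep(0, 48),
               tolerance = 1e-12)
  img2 <- generate_fiber_image(64, 64, angle = 45, coherence = 0.5, seed = 7)
  img3 <- generate_fiber_image(64, 64, angle = 45, coherence = 0.5, seed = 7)
  expect_identical(img2, img3)
  expect_error(generate_fiber_image(64, 64, angle = 180),
               class = "trajdyn_input_error")
  expect_error(generate_fiber_image(16, 64), class = "trajdyn_input_error")
})

test_that("suction curve construction pins the recovery fractions", {
  full <- compute_r_parameters(generate_suction_curve(
    uf = 0.3, elastic_fraction = 1, recovery_fraction = 1))
  expect_equal(full$R7, 1, tolerance = 1e-8)
  expect_equal(full$R2, 1, tolerance = 1e-8)
  none <- compute_r_parameters(generate_suction_curve(
    uf = 0.3, elastic_fraction = 0, recovery_fraction = 0))
  expect_equal(none$R7, 0, tolerance = 1e-8)
  expect_equal(none$R2, 0, tolerance = 1e-8)
  half <- compute_r_parameters(generate_suction_curve(
    uf = 0.3, elastic_fraction = 0.5, recovery_fraction = 0.8))
  expect_equal(half$R7, 0.5, tolerance = 1e-8)
  expect_equal(half$R2, 0.8, tolerance = 1e-8)
  expect_equal(half$Uf, 0.3, tolerance = 1e-12)
  expect_error(generate_suction_curve(elastic_fraction = 0.8,
                                      recovery_fraction = 0.5),
               class = "trajdyn_input_error")
})
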