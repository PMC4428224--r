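test_that("parcellation generation follows the design's module layout", {
  d <- simulation_design(nodes_per_module = reference_module_sizes(),
                         seed = 3L)
  p <- generate_parcellation(d)
  expect_equal(nrow(p), 209L)
  expect_equal(as.integer(table(p$module)),
               unname(reference_module_sizes()))
  expect_equal(levels(p$module), rsn_modules())

  d1 <- simulation_design(nodes_per_module = 2L, n_timepoints = 50)
  expect_equal(nrow(generate_parcellation(d1)), 2L)

  d3 <- simulation_design(nodes_per_module = c(4L, 5L, 6L))
  p3 <- generate_parcellation(d3)
  expect_equal(as.character(p3$module), rep(c("M1", "M2", "M3"), c(4, 5, 6)))

  expect_error(simulation_design(nodes_per_module = c(3L, 0L)),
               "at least one node")
})

test_that("identical design and seed give bit-identical cohorts", {
  d <- tiny_design(seed = 9L)
  c1 <- generate_group_timeseries(d)
  c2 <- generate_group_timeseries(tiny_design(seed = 9L))
  expect_identical(c1$series, c2$series)
  expect_identical(c1$group, c2$group)
})

test_that("adding subjects leaves existing subjects' series unchanged", {
  base <- generate_group_timeseries(tiny_design(seed = 5L))
  bigger <- generate_group_timeseries(
    simulation_design(n_subjects_per_group = 6L,
                      nodes_per_module = c(3L, 4L, 3L),
                      n_timepoints = 120L, seed = 5L))
  # first 4 subjects of each group must be untouched
  expect_identical(unname(base$series[1:4]), unname(bigger$series[1:4]))
  expect_identical(unname(base$series[5:8]), unname(bigger$series[7:10]))
})

test_that("sample correlations converge to the design targets", {
  d <- simulation_design(n_subjects_per_group = 2L,
                         nodes_per_module = c(3L, 3L),
                         n_timepoints = 10000L,
                         base_within_corr = 0.5,
                         base_between_corr = 0.1,
                         seed = 21L)
  ch <- generate_group_timeseries(d)
  R <- stats::cor(ch$series[[1]])
  within1 <- R[1:3, 1:3][upper.tri(diag(3))]
  within2 <- R[4:6, 4:6][upper.tri(diag(3))]
  expect_true(all(abs(c(within1, within2) - 0.5) < 0.05))
  expect_true(all(abs(R[1:3, 4:6] - 0.1) < 0.05))
})

test_that("with no planted effect both groups share one target matrix", {
  d <- tiny_design()
  expect_identical(d$target_corr[[1]], d$target_corr[[2]])
})

test_that("a planted positive delta raises group 1's block mean", {
  hits <- vapply(1:20, function(s) {
    d <- simulation_design(
      n_subjects_per_group = 3L, nodes_per_module = c(3L, 3L),
      n_timepoints = 5000L,
      planted_effects = list(list(module_a = 1, module_b = 2,
                                  delta = 0.3, group = 1)),
      seed = s)
    ch <- generate_group_timeseries(d)
    bm <- vapply(ch$series, function(x) {
      mean(stats::cor(x)[1:3, 4:6])
    }, 0)
    mean(bm[ch$group == "g1"]) > mean(bm[ch$group == "g2"])
  }, NA)
  expect_true(all(hits))
})

test_that("planted deltas must keep target correlations inside (-1, 1)", {
  expect_error(
    simulation_design(nodes_per_module = c(3L, 3L),
                      base_between_corr = 0.8,
                      planted_effects = list(list(module_a = 1, module_b = 2,
                                                  delta = 0.3, group = 1))),
    "outside")
})

test_that("PSD repair warns, stays within tolerance, and errors beyond it", {
  # slightly non-PSD 3x3 correlation matrix
  R <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.9, 0.2, 0.9, 1), 3, 3)
  expect_lt(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_warning(R2 <- modfc:::repair_correlation(R, tol = 0.2),
                 "not positive semi-definite")
  expect_gte(min(eigen(R2, symmetric = TRUE)$values), 0)
  expect_lte(max(abs(R2 - R)), 0.2)
  expect_equal(diag(R2), rep(1, 3))
  expect_error(suppressWarnings(modfc:::repair_correlation(R, tol = 1e-4)),
               "tolerance")
})

test_that("voxel expansion reduces to the latent series when noiseless", {
  s <- sin(seq_len(80) / 5)
  v <- generate_voxel_timeseries(s, 4L, 0, seed = 2L)
  expect_equal(dim(v), c(80L, 4L))
  expect_true(all(v == s))
  v1 <- generate_voxel_timeseries(s, 1L, 0.3, seed = 2L)
  expect_equal(dim(v1), c(80L, 1L))
  expect_false(all(v1 == s))
  expect_error(generate_voxel_timeseries(s, 0L, 0.1), ">= 1")
})

test_that("node-series extraction recovers the voxel latent series", {
  set.seed(4)
  latent <- as.numeric(scale(stats::rnorm(400)))
  v <- generate_voxel_timeseries(latent, 50L, 0.5, seed = 7L)
  rep_series <- extract_node_series(standardize_series(detrend_series(v)))
  expect_gt(stats::cor(rep_series, latent), 0.95)
})

test_that("behavior scores follow the linear coupling model", {
  coords <- matrix(stats::rnorm(48), 24, 2,
                   dimnames = list(NULL, c("A-A", "A-B")))
  # zero loading: pure noise, no systematic correlation
  b0 <- generate_behavior_scores(
    coords, list(list(blocks = "A-A", loadings = 0, noise_sd = 1)), seed = 1L)
  expect_lt(abs(stats::cor(b0[[2]], coords[, "A-A"])), 0.5)
  # noiseless single coupling: perfect correlation
  b1 <- generate_behavior_scores(
    coords, list(list(blocks = "A-B", loadings = -2, noise_sd = 0,
                      name = "rvip")), seed = 1L)
  expect_equal(abs(stats::cor(b1$rvip, coords[, "A-B"])), 1)
  expect_identical(
    b1, generate_behavior_scores(
      coords, list(list(blocks = "A-B", loadings = -2, noise_sd = 0,
                        name = "rvip")), seed = 1L))
  expect_error(generate_behavior_scores(
    coords, list(list(blocks = "missing", noise_sd = 0))), "not present")
})

test_that("coupling_noise_for_r hits the requested population correlation", {
  sd_c <- 2.5
  noise <- coupling_noise_for_r(sd_c, loading = 1.5, target_r = 0.6)
  implied_r <- 1.5 * sd_c / sqrt((1.5 * sd_c)^2 + noise^2)
  expect_equal(implied_r, 0.6)
})

test_that("cohort writers produce the documented plain-text layout", {
  ch <- generate_group_timeseries(tiny_design())
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "S01_timeseries.tsv")))
  expect_true(file.exists(file.path(dir, "parcellation.csv")))
  expect_true(file.exists(file.path(dir, "groups.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(gt$target_block_means, 2L)
})
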