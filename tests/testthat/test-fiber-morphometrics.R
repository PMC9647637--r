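# Skeletonization, skeleton graph and the 13 morphology metrics.

test_that("skeleton graph of canonical shapes: bar, T, ring", {
  g <- skeletonize_and_prune(make_bar(), pixel_size = 1)
  expect_equal(g$n_endpoints, 2)
  expect_equal(g$n_branchpoints, 0)
  expect_equal(total_skeleton_length(g), 100, tolerance = 2 / 100)

  tee <- matrix(FALSE, 120, 120)
  tee[19:21, 10:110] <- TRUE; tee[19:110, 59:61] <- TRUE
  g <- skeletonize_and_prune(tee, 1)
  expect_equal(g$n_endpoints, 3)
  expect_equal(g$n_branchpoints, 1)

  ann <- make_annulus()
  g <- skeletonize_and_prune(ann, 1)
  expect_equal(g$n_endpoints, 0)
  expect_equal(g$n_branchpoints, 0)
  expect_equal(length(g$edges), 1)                 # one closed cycle
  expect_equal(total_skeleton_length(g), 2 * pi * 100, tolerance = 0.05)
})

test_that("empty mask and pixel calibration are handled", {
  g <- skeletonize_and_prune(matrix(FALSE, 20, 20), 1)
  expect_equal(g$n_endpoints, 0)
  expect_equal(length(g$edges), 0)

  # calibration scales lengths
  g2 <- skeletonize_and_prune(make_bar(), pixel_size = 0.5)
  expect_equal(total_skeleton_length(g2), 50, tolerance = 0.02)
})

test_that("metric limits: filled plane, straight fiber, HGU identity", {
  full <- matrix(TRUE, 64, 64)
  sk <- skeletonize_and_prune(full, 1)
  m <- compute_metrics(full, sk, pixel_size = 1)
  expect_equal(m$density, 1)
  expect_equal(m$lacunarity, 1, tolerance = 1e-9)
  expect_equal(m$fractal_dimension, 2, tolerance = 0.05)

  fib <- matrix(FALSE, 64, 256); fib[32:33, 11:240] <- TRUE
  sk <- skeletonize_and_prune(fib, 1)
  m <- compute_metrics(fib, sk, pixel_size = 1)
  expect_gte(m$alignment, 0.95)
  expect_lt(abs(m$curvature), 1)
  expect_equal(m$fractal_dimension, 1, tolerance = 0.1)
  # HGU identity holds exactly
  expect_equal(m$hyphal_growth_unit * m$n_endpoints, m$total_length)
  expect_equal(m$hyphal_growth_unit, m$total_length / 2)
})

test_that("parallel fibers are coherent, isotropic fibers are not", {
  par_params <- fiber_phenotype_params(
    n_fibers = 120, mean_length = 60, orientation_kappa = 1e6,
    step_angle_sd = 0, branching_rate = 0, fiber_width = 2,
    target_coverage = 0.15)
  iso_params <- fiber_phenotype_params(
    n_fibers = 120, mean_length = 60, orientation_kappa = 0,
    step_angle_sd = 0, branching_rate = 0, fiber_width = 2,
    target_coverage = 0.15)
  pnet <- generate_fiber_network(par_params, c(160, 160), 1, seed = 5)
  inet <- generate_fiber_network(iso_params, c(160, 160), 1, seed = 5)
  a_par <- tmefib:::alignment_coherence(pnet$mask, matrix(TRUE, 160, 160))
  a_iso <- tmefib:::alignment_coherence(inet$mask, matrix(TRUE, 160, 160))
  expect_gt(a_par, 0.7)
  expect_lt(a_iso, 0.3)
  # oracle: orientation dispersion of the planted polylines themselves
  expect_lt(abs(sin(mean(pnet$orientations))), 0.05)
})

test_that("90-degree rotation leaves metrics nearly unchanged", {
  net <- generate_fiber_network(fiber_phenotype_preset("A"), c(160, 160),
                                1, seed = 11)
  rot <- t(net$mask)[, rev(seq_len(nrow(net$mask)))]
  m1 <- compute_metrics(net$mask, skeletonize_and_prune(net$mask, 1),
                        pixel_size = 1)
  m2 <- compute_metrics(rot, skeletonize_and_prune(rot, 1), pixel_size = 1)
  for (v in c("total_length", "density", "lacunarity",
              "fractal_dimension", "alignment"))
    expect_equal(m1[[v]], m2[[v]], tolerance = 0.02, label = v)
})

test_that("lacunarity decreases as coverage grows on nested masks", {
  ok <- 0; n_pairs <- 30
  for (i in seq_len(n_pairs)) {
    p_small <- fiber_phenotype_params(n_fibers = 40, mean_length = 40,
                                      fiber_width = 2,
                                      target_coverage = 0.08)
    netA <- generate_fiber_network(p_small, c(120, 120), 1, seed = 100 + i)
    netB <- generate_fiber_network(p_small, c(120, 120), 1, seed = 500 + i)
    maskB <- netA$mask | netB$mask         # A strictly nested in B
    lamA <- tmefib:::box_metrics(netA$mask, matrix(TRUE, 120, 120))$lac
    lamB <- tmefib:::box_metrics(maskB, matrix(TRUE, 120, 120))$lac
    if (lamA >= lamB - 1e-12) ok <- ok + 1
  }
  expect_gte(ok / n_pairs, 0.95)
})

test_that("mean gap diameter tracks spacing of a line grating", {
  m <- matrix(FALSE, 120, 120)
  m[seq(10, 110, by = 20), ] <- TRUE       # lines 20 px apart
  g <- compute_metrics(m, skeletonize_and_prune(m, 1), pixel_size = 1)
  # distance-transform maxima midway between lines: radius ~10 -> diam ~20
  expect_equal(g$mean_gap_diameter, 20, tolerance = 0.25)
})
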