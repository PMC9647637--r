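# Fiber-network generator, IHC renderer and cohort generator.

test_that("fiber orientations follow the planted von Mises concentration", {
  iso <- fiber_phenotype_params(n_fibers = 200, mean_length = 40,
                                orientation_kappa = 0, step_angle_sd = 0,
                                branching_rate = 0, fiber_width = 2,
                                target_coverage = 0.25)
  net <- generate_fiber_network(iso, c(256, 256), 1, seed = 2)
  th <- net$orientations
  # circular variance ~ 1 for isotropy (axial doubling not needed here)
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(R, 0.15)

  conc <- fiber_phenotype_params(n_fibers = 100, mean_length = 40,
                                 orientation_kappa = 1e6, step_angle_sd = 0,
                                 branching_rate = 0, fiber_width = 2,
                                 target_coverage = 0.15)
  net2 <- generate_fiber_network(conc, c(256, 256), 1, seed = 2)
  expect_true(all(abs(net2$orientations) < pi / 180))
})

test_that("fiber generation hits target coverage, is seed-deterministic, errors when unreachable", {
  p <- fiber_phenotype_preset("A")
  n1 <- generate_fiber_network(p, c(200, 200), 1, seed = 9)
  n2 <- generate_fiber_network(p, c(200, 200), 1, seed = 9)
  expect_identical(n1$mask, n2$mask)
  expect_equal(n1$coverage, p$target_coverage, tolerance = 0.1)

  n3 <- generate_fiber_network(p, c(200, 200), 1, seed = 10)
  expect_false(identical(n1$mask, n3$mask))

  tiny <- fiber_phenotype_params(n_fibers = 2, mean_length = 5,
                                 fiber_width = 1, target_coverage = 0.9)
  expect_error(generate_fiber_network(tiny, c(120, 120), 1, seed = 1),
               "limiting parameter")
})

test_that("IHC rendering books planted cells and honours zero densities", {
  rs <- region_set(list(
    list(poly = square_poly(10, 10, 80), role = "tumor", id = "tum1",
         lesion_id = "L1", tls_id = NA, stage = NA),
    list(poly = square_poly(110, 110, 80), role = "stroma", id = "str1",
         lesion_id = "L1", tls_id = NA, stage = NA)))
  out <- render_ihc(rs, list(tum1 = list(t = 100, b = 0, nuclei = 0),
                             str1 = list(t = 150, b = 50, nuclei = 20)),
                    dims = c(220, 220), seed = 3)
  tr <- out$truth
  expect_equal(tr$t_planted[tr$id == "tum1"], 100)
  expect_equal(tr$b_planted[tr$id == "tum1"], 0)
  expect_equal(tr$t_planted[tr$id == "str1"], 150)
  expect_equal(tr$b_planted[tr$id == "str1"], 50)

  blank <- render_ihc(rs, list(), dims = c(220, 220), seed = 3)
  expect_true(all(blank$image == 255))
  ar <- positive_pixel_areas(blank$image, square_poly(10, 10, 80),
                             chromogen_thresholds())
  expect_equal(ar$brown_area + ar$pink_area + ar$total_tissue_area, 0)
})

test_that("cohort generator plants the logistic TLS model and count model", {
  # null nodular effect: empirical log-OR near 0 (lesion table only)
  p0 <- cohort_gen_params(n_lesions = 10000, tls_logit_nodular = 0,
                          tls_logit_intercept = 0, seed = 21)
  co0 <- generate_cohort_lesions(p0)
  tab <- table(co0$nodular, co0$any_tls)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_lt(abs(lor), 0.15)

  # planted OR 10.29 recovered within 15%
  p1 <- cohort_gen_params(n_lesions = 10000, seed = 22)
  co1 <- generate_cohort_lesions(p1)
  tab1 <- table(co1$nodular, co1$any_tls)
  or <- tab1[2, 2] * tab1[1, 1] / (tab1[2, 1] * tab1[1, 2])
  expect_lt(abs(or - 10.29) / 10.29, 0.15)

  # full tables: reproducibility and validity
  co <- generate_cohort(cohort_gen_params(n_lesions = 25, seed = 5))
  co2 <- generate_cohort(cohort_gen_params(n_lesions = 25, seed = 5))
  expect_identical(co$tumors, co2$tumors)
  expect_true(all(co$tumors$til_count >= 0))
  expect_true(all(co$tumors$proximity[is.na(co$tumors$tls_id)] == "control"))
  expect_error(generate_cohort(cohort_gen_params(n_lesions = 1)),
               "at least 2")
})

test_that("H&E scene renders truth masks aligned with the image", {
  net <- generate_fiber_network(fiber_phenotype_preset("A"), c(160, 160),
                                1, seed = 3)
  sc <- render_he_scene(net, dims = c(160, 160), seed = 3)
  expect_equal(dim(sc$image_he), c(160, 160, 3))
  # fibers are eosin-dark: mean intensity under fiber mask below background
  fib_px <- sc$image_he[, , 2][sc$truth$fibrillary]
  bg_px <- sc$image_he[, , 2][sc$truth$background]
  expect_lt(mean(fib_px), mean(bg_px) - 20)
})
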