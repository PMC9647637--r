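# Stromal bands, proximity classes, control fields, combination rule.

test_that("stromal band around a disk tumor matches the analytic annulus", {
  n <- 300
  tumor <- circle_poly(150, 150, 100, n = 360)
  stroma <- matrix(TRUE, n, n)
  band <- stromal_band(tumor, stroma, pixel_size = 1, band_width = 30)
  expect_equal(band$area_um2, pi * (130^2 - 100^2), tolerance = 0.02)

  # empty stroma -> empty band (warning, not failure)
  expect_warning(b0 <- stromal_band(tumor, matrix(FALSE, n, n), 1, 30),
                 "empty")
  expect_equal(b0$area_um2, 0)
  expect_error(stromal_band(tumor, stroma, 1, band_width = 0))

  # nesting: narrower band is a subset of the wider one
  b20 <- stromal_band(tumor, stroma, 1, 20)
  expect_true(all(!b20$mask | band$mask))
})

test_that("proximity classification follows the 500-um edge-to-edge rule", {
  tum <- square_poly(0, 0, 50)
  tls_near <- list(square_poly(30, 30, 40))      # touching/overlapping
  expect_equal(classify_proximity(tum, tls_near, 1)$class, "proximal")

  tls_600 <- list(square_poly(650, 0, 40))       # 600 um away
  r <- classify_proximity(tum, tls_600, 1)
  expect_equal(r$class, "distal")
  expect_equal(r$distance_um, 600, tolerance = 1e-9)

  expect_equal(classify_proximity(tum, list(), 1)$class, "control")

  # monotone in cutoff: proximal set only grows
  expect_equal(classify_proximity(tum, tls_600, 1, cutoff_um = 700)$class,
               "proximal")
})

test_that("control field sampling is feasible, tumor-containing, seeded", {
  tissue <- matrix(TRUE, 700, 700)
  tumor <- matrix(FALSE, 700, 700); tumor[330:370, 330:370] <- TRUE
  f1 <- control_fov(tissue, tumor, 1, size_um = 500, seed = 7)
  f2 <- control_fov(tissue, tumor, 1, size_um = 500, seed = 7)
  expect_identical(f1, f2)
  mask <- rasterize_poly(f1, c(700, 700))
  expect_true(any(mask & tumor))
  expect_error(control_fov(matrix(TRUE, 300, 300), matrix(TRUE, 300, 300),
                           1, size_um = 500), "feasible")
})

test_that("combine_regions reproduces hand-computed sums and averages", {
  r1 <- metric_row(endpoints = 4, branchpoints = 2, total_length = 200,
                   n_edges = 5, mask_area = 100, alignment = 0.2)
  r2 <- metric_row(endpoints = 6, branchpoints = 3, total_length = 300,
                   n_edges = 10, mask_area = 300, alignment = 0.6)
  comb <- combine_regions(rbind(r1, r2))
  expect_equal(comb$n_endpoints, 10)
  expect_equal(comb$total_length, 500)
  expect_equal(comb$hyphal_growth_unit, 50)          # 500 / 10
  expect_equal(comb$alignment, 0.5)                  # (100*.2+300*.6)/400
  expect_equal(comb$avg_fiber_length, 500 / 15)
  expect_equal(comb$endpoint_branchpoint_ratio, 2)

  # identity on one row
  expect_identical(combine_regions(r1), r1)

  # permutation invariance and associativity (pattern metrics)
  r3 <- metric_row(endpoints = 1, branchpoints = 0, total_length = 80,
                   n_edges = 2, mask_area = 50, alignment = 0.9)
  p1 <- combine_regions(rbind(r1, r2, r3))
  p2 <- combine_regions(rbind(r3, r1, r2))
  expect_equal(p1$alignment, p2$alignment, tolerance = 1e-9)
  p3 <- combine_regions(rbind(combine_regions(rbind(r1, r2)), r3))
  for (m in c("alignment", "lacunarity", "density", "hdm",
              "total_length", "n_endpoints", "hyphal_growth_unit"))
    expect_equal(p1[[m]], p3[[m]], tolerance = 1e-9)
})

test_that("GeoJSON region round trip preserves polygons and roles", {
  rs <- region_set(list(
    list(poly = square_poly(5, 5, 20), role = "tumor", id = "t1",
         lesion_id = "L1", tls_id = "x1", stage = NA_character_),
    list(poly = circle_poly(50, 50, 10, 16), role = "tls", id = "x1",
         lesion_id = "L1", tls_id = NA_character_, stage = "primary")),
    pixel_size = 0.5)
  path <- tempfile(fileext = ".geojson")
  write_regions_geojson(rs, path)
  rs2 <- read_regions_geojson(path, pixel_size = 0.5)
  expect_equal(length(rs2$regions), 2)
  expect_equal(rs2$regions[[1]]$role, "tumor")
  expect_equal(rs2$regions[[2]]$stage, "primary")
  expect_equal(rs2$regions[[2]]$poly, unname(rs$regions[[2]]$poly),
               tolerance = 1e-9)
})
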