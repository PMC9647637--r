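# Positive-pixel IHC scoring, TLS records and TIL records.

test_that("positive-pixel areas: planted pixels, boundaries, monotonicity", {
  img <- array(255, dim = c(60, 60, 3))
  # plant 1000 brown px in a 40x25 block
  br <- CHROMOGEN_RGB_test("brown")
  for (ch in 1:3) img[1:40, 1:25, ch] <- br[ch]
  thr <- chromogen_thresholds()
  ar <- positive_pixel_areas(img, square_poly(0, 0, 60), thr)
  expect_equal(ar$brown_area, 1000)
  expect_equal(ar$pink_area, 0)
  expect_equal(ar$total_tissue_area, 1000)

  # all-white region
  blank <- array(255, dim = c(20, 20, 3))
  a0 <- positive_pixel_areas(blank, square_poly(0, 0, 20), thr)
  expect_equal(a0$total_tissue_area, 0)

  # hue exactly at centre + width is included (closed interval)
  hue_edge <- (thr$brown_hue + thr$brown_width) %% 1
  rgb_edge <- grDevices::hsv(hue_edge, 0.6, 0.6)
  cc <- grDevices::col2rgb(rgb_edge)
  img2 <- array(255, dim = c(10, 10, 3))
  for (ch in 1:3) img2[, , ch] <- cc[ch]
  a2 <- positive_pixel_areas(img2, square_poly(0, 0, 10), thr)
  expect_equal(a2$brown_area, 100)

  # widening hue width never decreases a class area
  thr_wide <- chromogen_thresholds(brown_width = 0.2)
  a3 <- positive_pixel_areas(img, square_poly(0, 0, 60), thr_wide)
  expect_gte(a3$brown_area, ar$brown_area)

  # region outside image fails
  expect_error(positive_pixel_areas(img, square_poly(50, 50, 30), thr),
               "outside")

  # additivity over a partition into left/right halves
  aL <- positive_pixel_areas(img, rbind(c(0, 0), c(30, 0), c(30, 60),
                                        c(0, 60)), thr)
  aR <- positive_pixel_areas(img, rbind(c(30, 0), c(60, 0), c(60, 60),
                                        c(30, 60)), thr)
  expect_equal(aL$brown_area + aR$brown_area, ar$brown_area)
})

test_that("count estimation: arithmetic and missing-data convention", {
  thr <- chromogen_thresholds(nominal_cell_area = 38)
  ct <- estimate_counts(list(brown_area = 3800, pink_area = 0), thr)
  expect_equal(ct$t_count, 100)
  ct2 <- estimate_counts(list(brown_area = 75 * 38, pink_area = 25 * 38),
                         thr)
  expect_equal(ct2$b_fraction, 0.25)
  ct0 <- estimate_counts(list(brown_area = 0, pink_area = 0), thr)
  expect_true(is.na(ct0$b_fraction))
})

test_that("TLS and tumor records recover planted compositions", {
  rs <- region_set(list(
    list(poly = square_poly(5, 5, 330), role = "tissue", id = "tis",
         lesion_id = "L1", tls_id = NA, stage = NA),
    list(poly = square_poly(20, 20, 150), role = "tls", id = "TLS1",
         lesion_id = "L1", tls_id = NA, stage = "primary"),
    list(poly = square_poly(200, 200, 120), role = "tumor", id = "TUM1",
         lesion_id = "L1", tls_id = "TLS1", stage = NA)))
  out <- render_ihc(rs, list(TLS1 = list(t = 105, b = 45, nuclei = 0),
                             TUM1 = list(t = 32, b = 8, nuclei = 0)),
                    dims = c(340, 340), seed = 8)
  slide <- annotated_slide(out$image, rs, pixel_size = 1)
  thr <- chromogen_thresholds()
  tls <- tls_properties(slide, thr)
  expect_equal(nrow(tls), 1)
  expect_equal(tls$stage, "primary")
  # planted B fraction 0.3 recovered within 0.05
  expect_lt(abs(tls$b_fraction - 0.3), 0.05)
  expect_equal(tls$area_mm2, 150^2 / 1e6, tolerance = 1e-9)
  expect_equal(tls$relative_size, 150^2 / 330^2, tolerance = 1e-6)

  tum <- til_counts(slide, thr)
  expect_equal(tum$proximity, "proximal")    # 50 um gap < 500
  expect_equal(tum$tls_id, "TLS1")
  # planted 40 cells recovered within 10% (overlap + rasterization)
  expect_lte(abs(tum$til_count - 40) / 40, 0.10)

  # control lesion: no TLS polygons
  rs_ctl <- region_set(list(
    list(poly = square_poly(10, 10, 60), role = "tumor", id = "C1",
         lesion_id = "L2", tls_id = NA, stage = NA)))
  blank <- array(255, dim = c(100, 100, 3))
  slide2 <- annotated_slide(blank, rs_ctl, 1)
  tum2 <- til_counts(slide2, thr)
  expect_equal(tum2$proximity, "control")
  expect_true(is.na(tum2$tls_id))
  expect_equal(tum2$til_count, 0)
})

test_that("primary-stage TLS records exceed aggregate-stage on planted contrasts", {
  co <- generate_cohort(cohort_gen_params(n_lesions = 40, seed = 30))
  tls <- co$tls
  expect_true(all(c("aggregate", "primary") %in% tls$stage))
  med <- function(v, s) median(v[tls$stage == s])
  expect_gt(med(tls$b_count, "primary"), med(tls$b_count, "aggregate"))
  expect_gt(med(tls$t_count + tls$b_count, "primary"),
            med(tls$t_count + tls$b_count, "aggregate"))
  expect_gt(med(tls$area_mm2, "primary"), med(tls$area_mm2, "aggregate"))
})

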