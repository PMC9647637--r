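# Feature stack, trainable classifier, probability maps, QC.

test_that("feature stack bookkeeping and degenerate inputs", {
  img <- matrix(0.5, 64, 64)
  fs <- compute_feature_stack(img, scales = c(1, 2))
  expect_equal(dim(fs)[3], 6 * 2 + 1)
  # constant image: all derivative/variance bands vanish
  for (b in dimnames(fs)[[3]][-(1:2)])
    if (!startsWith(b, "gauss")) expect_lt(max(abs(fs[, , b])), 1e-9)

  # ridge: Hessian low eigenvalue more negative on the ridge than off
  ridge <- matrix(0, 64, 64); ridge[32, ] <- 1
  fr <- compute_feature_stack(ridge, scales = 2)
  expect_gt(abs(fr[32, 32, "hess_lo_s2"]), abs(fr[10, 32, "hess_lo_s2"]))

  expect_error(compute_feature_stack(img, scales = 40), "image/4")
})

make_texture_scene <- function(seed = 1) {
  # linearly separable textures via intensity levels + noise
  set.seed(seed)
  img <- matrix(0.1, 96, 96)
  img[1:48, 1:48] <- 1.0          # "fibrillary"-bright
  img[49:96, 1:48] <- 0.5         # "mucin"-mid
  img <- img + matrix(rnorm(96 * 96, 0, 0.02), 96)
  truth <- matrix("background", 96, 96)
  truth[1:48, 1:48] <- "fibrillary"
  truth[49:96, 1:48] <- "mucin"
  list(img = img, truth = truth)
}

scribbles_from_truth <- function(truth, classes, n = 120, seed = 1) {
  set.seed(seed)
  out <- list()
  for (cl in classes) {
    px <- which(truth == cl, arr.ind = TRUE)
    out[[cl]] <- px[sample.int(nrow(px), n), , drop = FALSE]
  }
  out
}

test_that("classifier: separable textures, determinism, preconditions", {
  sc <- make_texture_scene()
  fs <- compute_feature_stack(sc$img, scales = c(1, 2))
  scr <- scribbles_from_truth(sc$truth,
                              c("fibrillary", "mucin", "background"))
  clf <- train_classifier(fs, scr, seed = 7)
  pred <- predict_maps(fs, clf)
  # probabilities sum to 1 per pixel
  expect_equal(max(abs(apply(pred$prob, c(1, 2), sum) - 1)), 0,
               tolerance = 1e-9)
  # training accuracy on scribbles
  acc <- mean(vapply(names(scr), function(cl)
    mean(pred$labels[scr[[cl]]] == cl), 0))
  expect_gte(acc, 0.95)

  # determinism and scribble-order invariance
  clf2 <- train_classifier(fs, scr[c(3, 1, 2)], seed = 7)
  pred2 <- predict_maps(fs, clf2)
  expect_identical(pred$labels, pred2$labels)

  expect_error(train_classifier(fs, scr["fibrillary"]), "2 classes")
  small <- scr; small$mucin <- small$mucin[1:10, , drop = FALSE]
  expect_error(train_classifier(fs, small), "mucin")
  fs3 <- compute_feature_stack(sc$img, scales = 1)
  expect_error(predict_maps(fs3, clf), "band manifest")
})

test_that("fibrillary mask on a rendered H&E scene overlaps truth (Dice)", {
  net <- generate_fiber_network(fiber_phenotype_preset("A"), c(192, 192),
                                1, seed = 13)
  sc <- render_he_scene(net, dims = c(192, 192), seed = 13, n_nuclei = 50,
                        n_mucin_blobs = 2)
  dec <- deconvolve(rgb_to_od(sc$image_he), stain_matrix())
  eos <- stain_channel(dec, "eosin")
  fs <- compute_feature_stack(eos, scales = c(1, 2))
  scr <- list()
  set.seed(14)
  for (cl in c("fibrillary", "nuclei", "mucin", "background")) {
    px <- which(sc$truth[[cl]], arr.ind = TRUE)
    scr[[cl]] <- px[sample.int(nrow(px), min(400, nrow(px))), ,
                    drop = FALSE]
  }
  clf <- train_classifier(fs, scr, seed = 14)
  pred <- predict_maps(fs, clf)
  inter <- sum(pred$fibrillary_mask & sc$truth$fibrillary)
  dice <- 2 * inter / (sum(pred$fibrillary_mask) + sum(sc$truth$fibrillary))
  expect_gte(dice, 0.85)
})

test_that("QC eligibility flags blur and low resolution", {
  net <- generate_fiber_network(fiber_phenotype_preset("B"), c(128, 128),
                                1, seed = 4)
  sc <- render_he_scene(net, dims = c(128, 128), seed = 4)
  sharp <- qc_eligibility(sc$image_he)
  expect_true(sharp$eligible)
  blurred <- array(0, dim = dim(sc$image_he))
  for (ch in 1:3) blurred[, , ch] <- tmefib:::gauss_smooth(sc$image_he[, , ch], 6)
  qb <- qc_eligibility(blurred)
  expect_false(qb$eligible)
  expect_true("blur" %in% qb$reasons)
  expect_lt(qb$laplacian_var, sharp$laplacian_var)

  tiny <- qc_eligibility(matrix(runif(100), 10, 10), min_resolution = 64)
  expect_false(tiny$eligible)
  expect_true("resolution" %in% tiny$reasons)
})
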