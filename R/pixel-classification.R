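# Trainable pixel classification of the eosin channel into
# {fibrillary, nuclei, mucin, amyloid, background}: a multi-scale filter
# bank plus a seeded, bagged decision-tree ensemble (no tree package is
# assumed; the CART learner is self-contained).

PIXEL_CLASSES <- c("fibrillary", "nuclei", "mucin", "amyloid", "background")

#' Multi-scale feature stack for pixel classification
#'
#' Per scale sigma: Gaussian smooth, gradient magnitude, Laplacian,
#' larger and smaller Hessian eigenvalue, local variance — plus the raw
#' channel, so `6 * length(scales) + 1` bands in a fixed, documented
#' order.
#'
#' @param channel single-channel numeric raster (e.g. eosin
#'   concentration).
#' @param scales vector of Gaussian sigmas in pixels.
#' @return 3-D array h x w x bands with band names.
#' @export
compute_feature_stack <- function(channel, scales = c(1, 2, 4)) {
  stopifnot(length(scales) >= 1)
  if (any(scales > min(dim(channel)) / 4))
    stop("scale sigma larger than image/4")
  bands <- list(raw = channel)
  for (s in scales) {
    g <- gauss_smooth(channel, s)
    gx <- fix_na_border(grad_x(g)); gy <- fix_na_border(grad_y(g))
    gxx <- fix_na_border(grad_x(gx)); gyy <- fix_na_border(grad_y(gy))
    gxy <- fix_na_border(grad_y(gx))
    tr <- gxx + gyy
    disc <- sqrt(pmax(0, (gxx - gyy)^2 + 4 * gxy^2))
    mu <- gauss_smooth(channel, 2 * s)
    mu2 <- gauss_smooth(channel^2, 2 * s)
    nm <- paste0(c("gauss", "gradmag", "laplacian", "hess_hi", "hess_lo",
                   "variance"), "_s", s)
    bands[[nm[1]]] <- g
    bands[[nm[2]]] <- sqrt(gx^2 + gy^2)
    bands[[nm[3]]] <- laplacian3(g)
    bands[[nm[4]]] <- (tr + disc) / 2
    bands[[nm[5]]] <- (tr - disc) / 2
    bands[[nm[6]]] <- pmax(0, mu2 - mu^2)
  }
  arr <- array(unlist(bands, use.names = FALSE),
               dim = c(nrow(channel), ncol(channel), length(bands)),
               dimnames = list(NULL, NULL, names(bands)))
  arr
}

# ---- minimal CART + bagging --------------------------------------------

gini_best_split <- function(x, yint, K, min_leaf) {
  o <- order(x)
  xs <- x[o]; ys <- yint[o]
  n <- length(xs)
  cum <- matrix(0, n, K)
  for (k in 1:K) cum[, k] <- cumsum(ys == k)
  tot <- cum[n, ]
  valid <- which(xs[-n] < xs[-1])          # split between distinct values
  valid <- valid[valid >= min_leaf & valid <= n - min_leaf]
  if (length(valid) == 0) return(NULL)
  nl <- valid
  nr <- n - nl
  gl <- 1 - rowSums((cum[valid, , drop = FALSE] / nl)^2)
  right <- matrix(tot, length(valid), K, byrow = TRUE) -
    cum[valid, , drop = FALSE]
  gr <- 1 - rowSums((right / nr)^2)
  imp <- (nl * gl + nr * gr) / n
  b <- which.min(imp)
  list(threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2,
       impurity = imp[b])
}

grow_tree <- function(X, yint, K, mtry, max_depth, min_node, depth = 0) {
  n <- length(yint)
  probs <- tabulate(yint, K) / n
  if (depth >= max_depth || n < min_node || max(probs) > 0.999)
    return(list(leaf = TRUE, probs = probs))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL
  for (f in feats) {
    sp <- gini_best_split(X[, f], yint, K, max(1L, min_node %/% 3L))
    if (!is.null(sp) && (is.null(best) || sp$impurity < best$impurity)) {
      best <- sp; best$feature <- f
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, probs = probs))
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[left, , drop = FALSE], yint[left], K, mtry,
                        max_depth, min_node, depth + 1),
       right = grow_tree(X[!left, , drop = FALSE], yint[!left], K, mtry,
                         max_depth, min_node, depth + 1))
}

predict_tree <- function(node, X, out, idx) {
  if (node$leaf) {
    out[idx, ] <- matrix(node$probs, length(idx), length(node$probs),
                         byrow = TRUE)
    return(out)
  }
  left <- X[idx, node$feature] <= node$threshold
  if (any(left)) out <- predict_tree(node$left, X, out, idx[left])
  if (any(!left)) out <- predict_tree(node$right, X, out, idx[!left])
  out
}

#' Train the pixel classifier from labelled scribbles
#'
#' A seeded, bagged ensemble of CART trees (gini splits, feature
#' subsampling) fit on the feature stack at scribbled pixel locations.
#'
#' @param features feature stack from [compute_feature_stack()].
#' @param scribbles named list of class -> integer matrix (r, c) of pixel
#'   coordinates; class names from the fixed vocabulary
#'   (fibrillary, nuclei, mucin, amyloid, background); >= 50 px per class.
#' @param seed integer seed (determinism contract).
#' @param n_trees,mtry,max_depth,min_node ensemble hyper-parameters.
#' @param max_per_class training pixels subsampled per class.
#' @return object of class `pixel_classifier` carrying the trees, the
#'   class order and the band manifest.
#' @export
train_classifier <- function(features, scribbles, seed = 1, n_trees = 20,
                             mtry = NULL, max_depth = 12, min_node = 10,
                             max_per_class = 1500) {
  bad <- setdiff(names(scribbles), PIXEL_CLASSES)
  if (length(bad) > 0) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (length(scribbles) < 2) stop("need scribbles for at least 2 classes")
  small <- names(scribbles)[vapply(scribbles, nrow, 0L) < 50]
  if (length(small) > 0)
    stop("fewer than 50 scribble pixels for class: ",
         paste(small, collapse = ", "))
  scribbles <- scribbles[order(names(scribbles))]   # order-invariance
  h <- dim(features)[1]
  nb_bands <- dim(features)[3]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Xs <- list(); ys <- list()
  classes <- names(scribbles)
  for (k in seq_along(classes)) {
    px <- scribbles[[k]]
    if (nrow(px) > max_per_class)
      px <- px[sample.int(nrow(px), max_per_class), , drop = FALSE]
    lin <- (px[, 2] - 1L) * h + px[, 1]
    M <- matrix(0, nrow(px), nb_bands)
    for (b in seq_len(nb_bands)) M[, b] <- features[, , b][lin]
    Xs[[k]] <- M; ys[[k]] <- rep(k, nrow(px))
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  K <- length(classes)
  if (is.null(mtry)) mtry <- max(2L, floor(sqrt(nb_bands)))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
    trees[[t]] <- grow_tree(X[boot, , drop = FALSE], y[boot], K, mtry,
                            max_depth, min_node)
  }
  structure(list(trees = trees, classes = classes,
                 bands = dimnames(features)[[3]], seed = seed),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier>", length(x$trees), "trees, classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Predict per-class probability maps and the fibrillary mask
#'
#' @param features feature stack with the same band manifest used for
#'   training.
#' @param classifier a [train_classifier()] artifact.
#' @param pixel_size um/px for the reported mask area.
#' @return list with `prob` (h x w x K array, per-pixel probabilities
#'   summing to 1), `labels` (argmax class matrix), `fibrillary_mask`
#'   and `fibrillary_area_um2`.
#' @export
predict_maps <- function(features, classifier, pixel_size = 1) {
  if (!identical(dimnames(features)[[3]], classifier$bands))
    stop("feature bands do not match the classifier's band manifest")
  h <- dim(features)[1]; w <- dim(features)[2]
  nb <- dim(features)[3]
  X <- matrix(features, h * w, nb)
  K <- length(classifier$classes)
  acc <- matrix(0, h * w, K)
  for (tr in classifier$trees)
    acc <- acc + predict_tree(tr, X, matrix(0, h * w, K), seq_len(h * w))
  acc <- acc / length(classifier$trees)
  lab_idx <- max.col(acc, ties.method = "first")
  labels <- matrix(classifier$classes[lab_idx], h, w)
  prob <- array(acc, dim = c(h, w, K),
                dimnames = list(NULL, NULL, classifier$classes))
  fib <- labels == "fibrillary"
  list(prob = prob, labels = labels, fibrillary_mask = fib,
       fibrillary_area_um2 = sum(fib) * pixel_size^2)
}

#' Image-quality eligibility check
#'
#' An image is ineligible when its blur metric (variance of the 3x3
#' Laplacian of the grayscale) falls below `min_laplacian_var` or when the
#' raster is smaller than `min_resolution` pixels on either side.
#'
#' @param img RGB array or single-channel matrix.
#' @param min_laplacian_var blur threshold.
#' @param min_resolution minimum side length in px.
#' @return list with `eligible` flag and character `reasons`.
#' @export
qc_eligibility <- function(img, min_laplacian_var = 1, min_resolution = 64) {
  g <- if (length(dim(img)) == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    else img
  reasons <- character(0)
  if (min(dim(g)) < min_resolution) reasons <- c(reasons, "resolution")
  lv <- stats::var(as.numeric(laplacian3(g)))
  if (lv < min_laplacian_var) reasons <- c(reasons, "blur")
  list(eligible = length(reasons) == 0, reasons = reasons,
       laplacian_var = lv)
}
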