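# Raster primitives shared by the imaging modules.
#
# Images are numeric matrices (single channel) or h x w x 3 arrays (RGB,
# 0..255), row = y with origin at the top-left; masks are logical matrices.
# Pixel (r, c) has centre (x, y) = (c - 0.5, r - 0.5) in pixel units.

#' Shift a matrix by whole pixels
#'
#' @param m matrix.
#' @param dr,dc row/column shift (positive = down/right).
#' @param fill value for vacated cells.
#' @return matrix of the same dimension.
#' @keywords internal
mat_shift <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Replicate-pad then 1-D filter every column; used for separable kernels.
filter_cols <- function(m, k) {
  half <- (length(k) - 1L) / 2L
  h <- nrow(m)
  padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                  m[rep(h, half), , drop = FALSE])
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  matrix(out[(half + 1L):(half + h), ], nrow = h)
}

#' Separable convolution with a symmetric 1-D kernel (replicate padding)
#' @keywords internal
conv_sep <- function(m, k) {
  t(filter_cols(t(filter_cols(m, k)), k))
}

gauss_kernel_1d <- function(sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a single-channel raster
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels.
#' @keywords internal
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gauss_kernel_1d(sigma))
}

# Central-difference gradients; replicate boundary.
grad_x <- function(m) (mat_shift(m, 0, -1, fill = NA) - mat_shift(m, 0, 1, fill = NA)) / 2
grad_y <- function(m) (mat_shift(m, -1, 0, fill = NA) - mat_shift(m, 1, 0, fill = NA)) / 2

fix_na_border <- function(m) {
  m[1, ] <- 0; m[nrow(m), ] <- 0; m[, 1] <- 0; m[, ncol(m)] <- 0
  m[is.na(m)] <- 0
  m
}

#' 3x3 discrete Laplacian
#' @keywords internal
laplacian3 <- function(m) {
  out <- mat_shift(m, 1, 0) + mat_shift(m, -1, 0) +
    mat_shift(m, 0, 1) + mat_shift(m, 0, -1) - 4 * m
  # zero out the one-pixel border where shifts padded with 0
  out[1, ] <- 0; out[nrow(out), ] <- 0; out[, 1] <- 0; out[, ncol(out)] <- 0
  out
}

#' Integral image (summed-area table) with a leading zero row/column
#' @keywords internal
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

#' Sums over all s x s gliding boxes via an integral image
#' @return matrix of box sums, one per top-left position.
#' @keywords internal
gliding_box_sums <- function(ii, s) {
  h <- nrow(ii) - 1L; w <- ncol(ii) - 1L
  r <- 1:(h - s + 1L); cc <- 1:(w - s + 1L)
  ii[r + s, cc + s, drop = FALSE] - ii[r, cc + s, drop = FALSE] -
    ii[r + s, cc, drop = FALSE] + ii[r, cc, drop = FALSE]
}

#' Disk structuring element
#' @keywords internal
disk_kernel <- function(radius) {
  r <- as.integer(ceiling(radius))
  x <- (-r):r
  d2 <- outer(x^2, x^2, "+")
  (d2 <= radius^2) * 1
}

#' Binary dilation by a disk via FFT convolution
#'
#' Zero-padded so there is no wrap-around; exact for binary inputs since
#' counts are integers thresholded at 0.5.
#' @keywords internal
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask & TRUE)
  k <- disk_kernel(radius)
  h <- nrow(mask); w <- ncol(mask)
  kh <- nrow(k); kw <- ncol(k)
  H <- stats::nextn(h + kh - 1L, 2); W <- stats::nextn(w + kw - 1L, 2)
  A <- matrix(0, H, W); A[1:h, 1:w] <- mask * 1
  B <- matrix(0, H, W); B[1:kh, 1:kw] <- k
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (H * W)
  off <- (kh - 1L) / 2L
  conv[(1:h) + off, (1:w) + off, drop = FALSE] > 0.5
}

# 1-D squared distance transform (lower envelope of parabolas).
dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform
#'
#' Distance (in pixels) from every FALSE pixel to the nearest TRUE pixel.
#' @param mask logical matrix of feature pixels.
#' @return numeric matrix of distances (0 on feature pixels).
#' @keywords internal
distance_transform <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  stopifnot(h >= 2, w >= 2)
  INF <- (h + w)^2
  # vertical pass: two vectorized sweeps give 1-D squared distance per column
  g <- matrix(INF, h, w)
  g[mask] <- 0
  d <- g[1, ]
  for (r in 2:h) { d <- pmin(g[r, ], (sqrt(d) + 1)^2); g[r, ] <- d }
  d <- g[h, ]
  for (r in (h - 1):1) { d <- pmin(g[r, ], (sqrt(d) + 1)^2); g[r, ] <- d }
  # horizontal pass: exact lower-envelope per row
  out <- matrix(0, h, w)
  for (r in 1:h) out[r, ] <- dt1d(g[r, ])
  sqrt(out)
}

#' Strict-ish local maxima of a raster (8-neighbourhood)
#' @keywords internal
local_maxima <- function(m, min_value = 0) {
  ok <- m > min_value
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (m >= mat_shift(m, dr, dc, fill = -Inf))
  }
  ok
}

#' Connected-component labelling (8-connectivity, BFS)
#' @keywords internal
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  nextlab <- 0L
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      for (p in cur) {
        r <- ((p - 1L) %% h) + 1L
        nb <- p + offs
        keep <- nb >= 1L & nb <= h * w
        # drop wrap-arounds across matrix columns
        nr <- ((nb - 1L) %% h) + 1L
        keep <- keep & abs(nr - r) <= 1L
        nb <- nb[keep]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        lab[nb] <- nextlab
        queue <- c(queue, nb)
      }
    }
  }
  lab
}
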