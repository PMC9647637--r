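# Polygon primitives: simple (non-self-intersecting) polygons stored as
# two-column matrices (x, y) in pixel coordinates, origin top-left,
# half-open [0, n). Physical distances are obtained via pixel_size (um/px).

#' Polygon area by the shoelace formula
#' @param poly two-column matrix of vertices (x, y); closing edge implied.
#' @return area in squared coordinate units.
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

poly_centroid <- function(poly) colMeans(poly[, 1:2, drop = FALSE])

#' Point-in-polygon test (even-odd rule), vectorized over points
#' @keywords internal
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon to a logical mask (scanline, even-odd)
#'
#' A pixel is inside when its centre (c - 0.5, r - 0.5) is inside the
#' polygon.
#' @param poly vertex matrix (x, y) in pixel coordinates.
#' @param dim c(height, width) of the target raster.
#' @return logical matrix.
#' @export
rasterize_poly <- function(poly, dim) {
  h <- dim[1]; w <- dim[2]
  mask <- matrix(FALSE, h, w)
  ys <- poly[, 2]
  r0 <- max(1L, floor(min(ys) + 0.5) + 1L)
  r1 <- min(h, ceiling(max(ys) + 0.5))
  if (r0 > r1) return(mask)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[j, 1]; y2 <- poly[j, 2]
  for (r in r0:r1) {
    y <- r - 0.5
    sel <- (y1 > y) != (y2 > y)
    if (!any(sel)) next
    xs <- x1[sel] + (y - y1[sel]) * (x2[sel] - x1[sel]) / (y2[sel] - y1[sel])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, floor(xs[k] + 0.5) + 1L)
      c1 <- min(w, ceiling(xs[k + 1] - 0.5) + 0L)
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

# squared distance from points to a segment, vectorized over points
point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  if (L2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
}

#' Minimum edge-to-edge distance between two polygons
#'
#' Zero when the polygons touch or overlap.
#' @return distance in coordinate units.
#' @export
poly_min_dist <- function(p1, p2) {
  if (any(point_in_poly(p1[, 1], p1[, 2], p2)) ||
      any(point_in_poly(p2[, 1], p2[, 2], p1))) return(0)
  best <- Inf
  for (pair in list(list(p1, p2), list(p2, p1))) {
    a <- pair[[1]]; b <- pair[[2]]
    n <- nrow(b); j <- c(n, seq_len(n - 1L))
    for (e in seq_len(n)) {
      d2 <- point_seg_dist2(a[, 1], a[, 2], b[j[e], 1], b[j[e], 2],
                            b[e, 1], b[e, 2])
      best <- min(best, min(d2))
    }
  }
  sqrt(best)
}

#' Uniform random points inside a polygon (rejection sampling)
#' @keywords internal
sample_in_poly <- function(n, poly, margin = 0) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, 0, 2)
  guard <- 0
  while (nrow(out) < n && guard < 1000) {
    m <- max(2L * (n - nrow(out)), 32L)
    px <- stats::runif(m, xr[1] + margin, xr[2] - margin)
    py <- stats::runif(m, yr[1] + margin, yr[2] - margin)
    keep <- point_in_poly(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
    guard <- guard + 1
  }
  if (nrow(out) < n) stop("could not place points inside polygon")
  colnames(out) <- c("x", "y")
  out[seq_len(n), , drop = FALSE]
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Read a region set from a GeoJSON FeatureCollection
#'
#' Features must be Polygons; properties `role`, `id`, `lesion_id`,
#' `tls_id`, `stage` are picked up when present.
#' @param path file path.
#' @param pixel_size calibration in um/px attached to the region set.
#' @return a `region_set` (see [region_set()]).
#' @export
read_regions_geojson <- function(path, pixel_size = 1) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  regions <- lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON rings repeat the first vertex
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    pr <- f$properties
    list(poly = poly,
         role = pr$role %||% "tissue",
         id = pr$id %||% NA_character_,
         lesion_id = pr$lesion_id %||% NA_character_,
         tls_id = pr$tls_id %||% NA_character_,
         stage = pr$stage %||% NA_character_)
  })
  region_set(regions, pixel_size = pixel_size)
}

#' Write a region set as a GeoJSON FeatureCollection
#' @param rs a `region_set`.
#' @param path output path.
#' @export
write_regions_geojson <- function(rs, path) {
  features <- lapply(rs$regions, function(rg) {
    ring <- rbind(rg$poly, rg$poly[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))),
         properties = list(role = rg$role, id = rg$id,
                           lesion_id = rg$lesion_id, tls_id = rg$tls_id,
                           stage = rg$stage))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
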