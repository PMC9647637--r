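# Mask algebra around tumors: peritumoral stromal bands, TLS proximity
# classes, control fields, and the per-tumor combination rule for fiber
# metrics measured on several stromal fragments.

REGION_ROLES <- c("tumor", "tls", "stroma", "control_fov", "tissue")

#' Construct a region set
#'
#' A region set bundles role-labelled simple polygons with the raster
#' calibration. Each region is a list with elements `poly` (two-column
#' vertex matrix in pixel coordinates), `role`, `id`, `lesion_id`,
#' `tls_id` (link from a tumor to its nearest TLS) and `stage`.
#'
#' @param regions list of region lists as above.
#' @param pixel_size calibration in micrometres per pixel (> 0).
#' @return object of class `region_set`.
#' @export
region_set <- function(regions, pixel_size = 1) {
  stopifnot(pixel_size > 0)
  for (rg in regions) {
    stopifnot(is.matrix(rg$poly), ncol(rg$poly) == 2, nrow(rg$poly) >= 3)
    if (!(rg$role %in% REGION_ROLES))
      stop("unknown region role: ", rg$role)
  }
  structure(list(regions = regions, pixel_size = pixel_size),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  roles <- vapply(x$regions, `[[`, "", "role")
  cat("<region_set>", length(x$regions), "regions at", x$pixel_size,
      "um/px\n")
  print(table(roles))
  invisible(x)
}

regions_with_role <- function(rs, role) {
  rs$regions[vapply(rs$regions, function(r) r$role == role, TRUE)]
}

#' Peritumoral stromal band
#'
#' The band is the morphological dilation of the tumor polygon by
#' `band_width` micrometres, minus the tumor, intersected with the stroma
#' mask: the annular stromal margin used to sample fibrillary morphology
#' around a tumor nest.
#'
#' @param tumor_poly tumor polygon (pixel coordinates).
#' @param stroma_mask logical raster of stromal tissue.
#' @param pixel_size um/px.
#' @param band_width band width in micrometres (default 30).
#' @return list with `mask` (logical raster) and `area_um2`.
#' @export
stromal_band <- function(tumor_poly, stroma_mask, pixel_size,
                         band_width = 30) {
  stopifnot(band_width > 0, pixel_size > 0)
  dims <- dim(stroma_mask)
  tumor_mask <- rasterize_poly(tumor_poly, dims)
  radius <- round(band_width / pixel_size)
  band <- dilate_disk(tumor_mask, radius) & !tumor_mask & stroma_mask
  if (!any(band))
    warning("stromal band is empty (tumor fills the stroma?)")
  list(mask = band, area_um2 = sum(band) * pixel_size^2)
}

#' Classify a tumor's proximity to TLS
#'
#' Edge-to-edge distance to the nearest TLS polygon; "proximal" within
#' `cutoff_um` (default 500 um), "distal" beyond it, "control" when the
#' lesion carries no TLS.
#'
#' @param tumor_poly tumor polygon.
#' @param tls_polys list of TLS polygons on the same lesion (possibly
#'   empty).
#' @param pixel_size um/px.
#' @param cutoff_um proximity cutoff in micrometres.
#' @param strict_farthest when TRUE only the single maximum-distance tumor
#'   of a lesion should be called distal; this function then reports the
#'   distance and the caller applies the argmax rule.
#' @return list with `class` in {proximal, distal, control}, `distance_um`
#'   (NA for control) and `nearest_tls` index.
#' @export
classify_proximity <- function(tumor_poly, tls_polys, pixel_size,
                               cutoff_um = 500, strict_farthest = FALSE) {
  if (length(tls_polys) == 0)
    return(list(class = "control", distance_um = NA_real_,
                nearest_tls = NA_integer_))
  d <- vapply(tls_polys, function(p) poly_min_dist(tumor_poly, p), 0)
  d_um <- d * pixel_size
  i <- which.min(d_um)
  cls <- if (d_um[i] <= cutoff_um) "proximal" else "distal"
  list(class = cls, distance_um = d_um[i], nearest_tls = i)
}

#' Sample a control field of view
#'
#' Uniformly samples an axis-aligned square of side `size_um` lying fully
#' inside the tissue mask and containing at least one tumor pixel; used on
#' lesions without TLS.
#'
#' @param tissue_mask logical raster of tissue.
#' @param tumor_mask logical raster of tumor pixels.
#' @param pixel_size um/px.
#' @param size_um side length in micrometres (default 500).
#' @param seed integer seed controlling the placement.
#' @return square polygon (pixel coordinates).
#' @export
control_fov <- function(tissue_mask, tumor_mask, pixel_size,
                        size_um = 500, seed = 1) {
  s <- round(size_um / pixel_size)
  h <- nrow(tissue_mask); w <- ncol(tissue_mask)
  if (s > h || s > w) stop("no feasible control field: raster smaller than field")
  ii_t <- integral_image(tissue_mask * 1)
  ii_u <- integral_image(tumor_mask * 1)
  all_tissue <- gliding_box_sums(ii_t, s) == s^2
  has_tumor <- gliding_box_sums(ii_u, s) >= 1
  feas <- which(all_tissue & has_tumor)
  if (length(feas) == 0) stop("no feasible control field placement")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- feas[sample.int(length(feas), 1)]
  nr <- nrow(all_tissue)
  r0 <- ((pick - 1) %% nr)       # zero-based top row
  c0 <- ((pick - 1) %/% nr)      # zero-based left col
  rect_poly(c0, r0, c0 + s, r0 + s)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Metric classes for the combination rule -------------------------------

ADDITIVE_METRICS <- c("n_endpoints", "n_branchpoints", "total_length",
                      "mask_area")
RATIO_METRICS <- c("endpoint_branchpoint_ratio", "avg_fiber_length",
                   "hyphal_growth_unit")
PATTERN_METRICS <- c("curvature", "alignment", "fractal_dimension",
                     "lacunarity", "density", "hdm", "mean_gap_diameter")

#' Combine fiber metrics from several stromal fragments of one tumor
#'
#' Additive single-fiber measurements (endpoint/branchpoint counts, total
#' length, mask area) are summed; ratio measurements are recomputed from
#' the combined sums (so the hyphal-growth-unit identity
#' HGU = total length / endpoints survives combination); global pattern
#' measurements (curvature, alignment, lacunarity, density, HDM, fractal
#' dimension, mean gap) are averaged weighted by fibrillary-mask area.
#'
#' @param rows data.frame of fiber metric rows (see [compute_metrics()]),
#'   one per stromal fragment, each carrying `mask_area` and `n_edges`.
#' @return single combined row (data.frame).
#' @export
combine_regions <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  if (nrow(rows) == 1) return(rows)
  out <- rows[1, , drop = FALSE]
  for (m in intersect(ADDITIVE_METRICS, names(rows)))
    out[[m]] <- sum(rows[[m]])
  if ("n_edges" %in% names(rows)) out$n_edges <- sum(rows$n_edges)
  if ("roi_area" %in% names(rows)) out$roi_area <- sum(rows$roi_area)
  w <- rows$mask_area
  for (m in intersect(PATTERN_METRICS, names(rows))) {
    if (sum(w) > 0) {
      out[[m]] <- sum(w * rows[[m]]) / sum(w)
    } else {
      out[[m]] <- NA_real_
    }
  }
  # ratios recomputed from combined sums
  out$endpoint_branchpoint_ratio <- out$n_endpoints / max(out$n_branchpoints, 1)
  out$avg_fiber_length <- if (isTRUE(out$n_edges > 0))
    out$total_length / out$n_edges else NA_real_
  out$hyphal_growth_unit <- if (out$n_endpoints > 0)
    out$total_length / out$n_endpoints else NA_real_
  rownames(out) <- NULL
  out
}
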