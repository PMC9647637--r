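# Positive-pixel quantification of dual-chromogen IHC (brown T cells,
# pink B cells, blue hematoxylin counterstain) inside annotated regions,
# and the derived TLS / tumor (TIL) records.

#' Chromogen thresholds for positive-pixel counting
#'
#' Hue centres/widths are on the circular `[0, 1)` hue scale; a pixel is
#' positive for a class when its hue lies within centre +/- width (closed
#' interval), saturation >= `min_saturation` and value <= `max_value`.
#' Defaults are calibrated against the package's synthetic chromogen
#' constants (DAB-like brown, fast-red-like pink, hematoxylin-like blue)
#' and are held constant across a project run.
#'
#' @param brown_hue,brown_width brown (T cell) hue window.
#' @param pink_hue,pink_width pink (B cell) hue window.
#' @param blue_hue,blue_width hematoxylin window (total-tissue area).
#' @param min_saturation minimum saturation for any positive pixel.
#' @param max_value maximum HSV value (stained pixels are darker than
#'   background).
#' @param nominal_cell_area area of one lymphocyte in um^2 used to convert
#'   integrated positive area to a cell-count estimate (default 38, a
#'   7-um disk).
#' @return object of class `chromogen_thresholds`.
#' @export
chromogen_thresholds <- function(brown_hue = 0.083, brown_width = 0.10,
                                 pink_hue = 0.93, pink_width = 0.08,
                                 blue_hue = 0.64, blue_width = 0.15,
                                 min_saturation = 0.15, max_value = 0.97,
                                 nominal_cell_area = 38) {
  stopifnot(brown_width < 0.5, pink_width < 0.5, blue_width < 0.5,
            nominal_cell_area > 0)
  structure(list(brown_hue = brown_hue, brown_width = brown_width,
                 pink_hue = pink_hue, pink_width = pink_width,
                 blue_hue = blue_hue, blue_width = blue_width,
                 min_saturation = min_saturation, max_value = max_value,
                 nominal_cell_area = nominal_cell_area),
            class = "chromogen_thresholds")
}

hue_in_window <- function(h, centre, width) {
  d <- abs(h - centre)
  pmin(d, 1 - d) <= width + 1e-12     # closed interval, circular
}

#' An annotated slide: calibrated image plus role-labelled regions
#' @param image h x w x 3 RGB array (0..255).
#' @param regions a [region_set()] in the image's pixel coordinates.
#' @param pixel_size um/px.
#' @export
annotated_slide <- function(image, regions, pixel_size = 1) {
  stopifnot(length(dim(image)) == 3, inherits(regions, "region_set"))
  for (rg in regions$regions) {
    if (any(rg$poly[, 1] < 0 | rg$poly[, 1] > dim(image)[2] |
            rg$poly[, 2] < 0 | rg$poly[, 2] > dim(image)[1]))
      stop("polygon outside raster for region ", rg$id)
  }
  structure(list(image = image, regions = regions,
                 pixel_size = pixel_size), class = "annotated_slide")
}

#' Positive-pixel areas inside a region
#'
#' Classifies every pixel of the region by HSV windows: brown (T),
#' pink (B) — mutually exclusive with brown precedence on ties — and
#' hematoxylin-stained; areas in um^2. Total tissue area is the union of
#' the three stained classes.
#'
#' @param image RGB array (0..255).
#' @param region_poly polygon in pixel coordinates.
#' @param thresholds a [chromogen_thresholds()].
#' @param pixel_size um/px.
#' @param exclusion_mask optional logical raster of pixels to ignore
#'   (e.g. melanin).
#' @return list with `brown_area`, `pink_area`, `hematoxylin_area`,
#'   `total_tissue_area` (um^2) and pixel counts.
#' @export
positive_pixel_areas <- function(image, region_poly, thresholds,
                                 pixel_size = 1, exclusion_mask = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(region_poly[, 1] < 0 | region_poly[, 1] > w |
          region_poly[, 2] < 0 | region_poly[, 2] > h))
    stop("region polygon outside image")
  sel <- rasterize_poly(region_poly, c(h, w))
  if (!is.null(exclusion_mask)) sel <- sel & !exclusion_mask
  idx <- which(sel)
  if (length(idx) == 0)
    return(list(brown_area = 0, pink_area = 0, hematoxylin_area = 0,
                total_tissue_area = 0, n_brown = 0L, n_pink = 0L))
  hsv <- grDevices::rgb2hsv(image[, , 1][idx], image[, , 2][idx],
                            image[, , 3][idx], maxColorValue = 255)
  stained <- hsv[2, ] >= thresholds$min_saturation &
    hsv[3, ] <= thresholds$max_value
  brown <- stained & hue_in_window(hsv[1, ], thresholds$brown_hue,
                                   thresholds$brown_width)
  pink <- stained & !brown &
    hue_in_window(hsv[1, ], thresholds$pink_hue, thresholds$pink_width)
  blue <- stained & !brown & !pink &
    hue_in_window(hsv[1, ], thresholds$blue_hue, thresholds$blue_width)
  a <- pixel_size^2
  list(brown_area = sum(brown) * a, pink_area = sum(pink) * a,
       hematoxylin_area = sum(blue) * a,
       total_tissue_area = sum(brown | pink | blue) * a,
       n_brown = sum(brown), n_pink = sum(pink))
}

#' Convert integrated positive areas to cell-count estimates
#'
#' @param areas result of [positive_pixel_areas()].
#' @param thresholds a [chromogen_thresholds()] (for
#'   `nominal_cell_area`).
#' @return list with `t_count`, `b_count`, `b_fraction` (NA when both
#'   counts are zero — missing, not 0).
#' @export
estimate_counts <- function(areas, thresholds) {
  t_count <- round(areas$brown_area / thresholds$nominal_cell_area)
  b_count <- round(areas$pink_area / thresholds$nominal_cell_area)
  b_fraction <- if (t_count + b_count > 0) b_count / (t_count + b_count)
    else NA_real_
  list(t_count = t_count, b_count = b_count, b_fraction = b_fraction)
}

#' TLS records for a slide
#'
#' One record per TLS polygon: estimated T/B counts, B fraction, area in
#' mm^2 and size relative to the tissue polygon.
#'
#' @param slide an [annotated_slide()].
#' @param thresholds a [chromogen_thresholds()].
#' @return data.frame with one row per TLS (ordered by id).
#' @export
tls_properties <- function(slide, thresholds = chromogen_thresholds()) {
  tls <- regions_with_role(slide$regions, "tls")
  if (length(tls) == 0) stop("no TLS polygons on slide")
  tissue <- regions_with_role(slide$regions, "tissue")
  tissue_area <- if (length(tissue) > 0)
    sum(vapply(tissue, function(r) poly_area(r$poly), 0)) *
      slide$pixel_size^2
  else { warning("no tissue polygon; relative_size missing"); NA_real_ }
  rows <- lapply(tls, function(rg) {
    ar <- positive_pixel_areas(slide$image, rg$poly, thresholds,
                               slide$pixel_size)
    ct <- estimate_counts(ar, thresholds)
    area_um2 <- poly_area(rg$poly) * slide$pixel_size^2
    data.frame(tls_id = rg$id, stage = rg$stage,
               area_mm2 = area_um2 / 1e6,
               t_count = ct$t_count, b_count = ct$b_count,
               b_fraction = ct$b_fraction,
               relative_size = area_um2 / tissue_area)
  })
  out <- do.call(rbind, rows)
  out[order(out$tls_id), , drop = FALSE]
}

#' TIL (tumor record) table for a slide
#'
#' For every tumor polygon: TIL count (T + B inside the tumor), tumor
#' area, and proximity class to the lesion's TLS set (proximal within
#' `cutoff_um`, distal beyond, control when the lesion has no TLS).
#'
#' @param slide an [annotated_slide()].
#' @param thresholds a [chromogen_thresholds()].
#' @param cutoff_um proximity cutoff (default 500).
#' @return data.frame of tumor records.
#' @export
til_counts <- function(slide, thresholds = chromogen_thresholds(),
                       cutoff_um = 500) {
  tumors <- regions_with_role(slide$regions, "tumor")
  if (length(tumors) == 0) stop("no tumor polygons on slide")
  tls <- regions_with_role(slide$regions, "tls")
  tls_polys <- lapply(tls, `[[`, "poly")
  rows <- list()
  for (rg in tumors) {
    area_um2 <- poly_area(rg$poly) * slide$pixel_size^2
    if (area_um2 <= 0) { warning("tumor ", rg$id, " has zero area; skipped"); next }
    ar <- positive_pixel_areas(slide$image, rg$poly, thresholds,
                               slide$pixel_size)
    ct <- estimate_counts(ar, thresholds)
    px <- classify_proximity(rg$poly, tls_polys, slide$pixel_size,
                             cutoff_um)
    rows[[length(rows) + 1L]] <- data.frame(
      tumor_id = rg$id, lesion_id = rg$lesion_id,
      tls_id = if (px$class == "control") NA_character_
        else tls[[px$nearest_tls]]$id,
      proximity = px$class, distance_um = px$distance_um,
      til_count = ct$t_count + ct$b_count, tumor_area_um2 = area_um2)
  }
  do.call(rbind, rows)
}

#' Heuristic TLS stage suggestion (never overrides annotation)
#'
#' Flags a TLS as "primary-like" when its pink (B cell) positive pixels
#' contain a connected component of at least `cluster_min_b` pixels —
#' B cells organized in a cluster rather than scattered. Staging proper is
#' a pathologist call consumed from annotations.
#'
#' @param slide an [annotated_slide()].
#' @param tls_id id of the TLS region.
#' @param thresholds a [chromogen_thresholds()].
#' @param cluster_min_b minimum B-positive component size in px.
#' @return "primary-like" or "aggregate-like".
#' @export
suggest_stage <- function(slide, tls_id,
                          thresholds = chromogen_thresholds(),
                          cluster_min_b = 200) {
  tls <- regions_with_role(slide$regions, "tls")
  rg <- tls[[which(vapply(tls, `[[`, "", "id") == tls_id)]]
  h <- dim(slide$image)[1]; w <- dim(slide$image)[2]
  sel <- rasterize_poly(rg$poly, c(h, w))
  hsv <- grDevices::rgb2hsv(slide$image[, , 1] * 1, slide$image[, , 2] * 1,
                            slide$image[, , 3] * 1, maxColorValue = 255)
  pinkv <- hsv[2, ] >= thresholds$min_saturation &
    hsv[3, ] <= thresholds$max_value &
    hue_in_window(hsv[1, ], thresholds$pink_hue, thresholds$pink_width)
  pink <- matrix(pinkv, h, w) & sel
  lab <- label_components(pink)
  if (max(lab) > 0 && max(tabulate(lab[lab > 0])) >= cluster_min_b)
    "primary-like" else "aggregate-like"
}
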