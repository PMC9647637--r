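# Shared fixtures, built in code at test time.

# axis-aligned bar mask (length_px wide along columns, thickness rows)
make_bar <- function(h = 40, w = 120, rows = 19:21, cols = 10:110) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# annulus centred in a square raster
make_annulus <- function(n = 256, r_in = 95, r_out = 105) {
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- t(x)
  d2 <- (x - n / 2)^2 + (y - n / 2)^2
  d2 >= r_in^2 & d2 <= r_out^2
}

# filled disk mask
make_disk <- function(n, r, cx = n / 2, cy = n / 2) {
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- t(x)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# circular polygon approximation (pixel coordinates)
circle_poly <- function(cx, cy, r, n = 90) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

square_poly <- function(x0, y0, side) {
  cbind(x = c(x0, x0 + side, x0 + side, x0),
        y = c(y0, y0, y0 + side, y0 + side))
}

# one-row fiber-metric stub for combination tests
metric_row <- function(endpoints, branchpoints, total_length, n_edges,
                       mask_area, alignment = 0.5, curvature = 10,
                       lacunarity = 2, density = 0.3, hdm = 0.2,
                       fractal_dimension = 1.5, mean_gap_diameter = 8,
                       roi_area = 1e4) {
  data.frame(n_endpoints = endpoints, n_branchpoints = branchpoints,
             endpoint_branchpoint_ratio = endpoints / max(branchpoints, 1),
             total_length = total_length,
             avg_fiber_length = total_length / max(n_edges, 1),
             hyphal_growth_unit = if (endpoints > 0)
               total_length / endpoints else NA_real_,
             curvature = curvature, alignment = alignment,
             fractal_dimension = fractal_dimension, lacunarity = lacunarity,
             density = density, hdm = hdm,
             mean_gap_diameter = mean_gap_diameter, mask_area = mask_area,
             roi_area = roi_area, n_edges = n_edges)
}

total_skeleton_length <- function(g) {
  if (length(g$edges) == 0) 0 else sum(vapply(g$edges, `[[`, 0, "length_um"))
}

# reach package-internal constants without exporting them
CHROMOGEN_RGB_test <- function(name) tmefib:::CHROMOGEN_RGB[[name]]
METRIC_COLUMNS_test <- function() tmefib:::METRIC_COLUMNS
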