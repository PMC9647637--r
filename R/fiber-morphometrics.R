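# Fibrillary-matrix morphometrics: topological thinning of a binary fiber
# mask to a 1-px skeleton, a pruned skeleton graph (endpoints, branch
# clusters, traced paths), and the 13 morphology metrics computed from it.

# value at (r + dr, c + dc), zero outside
nb <- function(m, dr, dc) mat_shift(m, -dr, -dc, fill = 0)

neighbor_count <- function(skel) {
  s <- skel * 1
  nb(s, -1, 0) + nb(s, -1, 1) + nb(s, 0, 1) + nb(s, 1, 1) +
    nb(s, 1, 0) + nb(s, 1, -1) + nb(s, 0, -1) + nb(s, -1, -1)
}

# Zhang-Suen thinning, fully vectorized over the raster.
thin_mask <- function(mask) {
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- nb(m, -1, 0);  P3 <- nb(m, -1, 1); P4 <- nb(m, 0, 1)
      P5 <- nb(m, 1, 1);   P6 <- nb(m, 1, 0);  P7 <- nb(m, 1, -1)
      P8 <- nb(m, 0, -1);  P9 <- nb(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (sub == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# Reduce a thinned raster to a minimal 8-connected skeleton: sequentially
# delete pixels whose remaining neighbors form a single 8-connected
# component (staircase corners Zhang-Suen leaves behind would otherwise
# read as spurious branchpoints).
minimal_skeleton <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  offs <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1), c(0, 1, 1, 1, 0, -1, -1, -1))
  repeat {
    s <- skel * 1
    ring <- list(nb(s, -1, 0), nb(s, -1, 1), nb(s, 0, 1), nb(s, 1, 1),
                 nb(s, 1, 0), nb(s, 1, -1), nb(s, 0, -1), nb(s, -1, -1))
    nn <- Reduce(`+`, ring)
    adjpair <- Reduce(`+`, lapply(1:8, function(k)
      ring[[k]] * ring[[if (k == 8) 1 else k + 1]]))
    cand <- which(skel & nn >= 2 & adjpair >= 1)
    if (length(cand) == 0) break
    changed <- FALSE
    for (p in cand) {
      r <- ((p - 1L) %% h) + 1L; c <- ((p - 1L) %/% h) + 1L
      pts <- cbind(r + offs[, 1], c + offs[, 2])
      ok <- pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w
      pts <- pts[ok, , drop = FALSE]
      pts <- pts[skel[pts], , drop = FALSE]
      n <- nrow(pts)
      if (n < 2) next
      # union-find over mutual 8-adjacency
      comp <- seq_len(n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (max(abs(pts[i, ] - pts[j, ])) <= 1) {
          ci <- comp[i]; cj <- comp[j]
          if (ci != cj) comp[comp == cj] <- ci
        }
      }
      if (length(unique(comp)) == 1) { skel[r, c] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  skel
}

# March each endpoint outwards into the original mask to recover the end
# pixels topological thinning erodes from fiber tips.
extend_ends <- function(skel, mask, max_steps = 8L) {
  h <- nrow(skel); w <- ncol(skel)
  nn <- neighbor_count(skel)
  ends <- which(skel & nn == 1, arr.ind = TRUE)
  for (k in seq_len(nrow(ends))) {
    e <- ends[k, ]
    # local direction: from the centroid of nearby skeleton pixels to e
    r0 <- max(1, e[1] - 4):min(h, e[1] + 4)
    c0 <- max(1, e[2] - 4):min(w, e[2] + 4)
    loc <- which(skel[r0, c0, drop = FALSE], arr.ind = TRUE)
    loc <- cbind(loc[, 1] + min(r0) - 1L, loc[, 2] + min(c0) - 1L)
    ctr <- colMeans(loc)
    dir <- c(e[1] - ctr[1], e[2] - ctr[2])
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) next
    dir <- dir / nrm
    for (t in seq_len(max_steps)) {
      p <- round(e + t * dir)
      if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) break
      if (!mask[p[1], p[2]] || skel[p[1], p[2]]) break
      skel[p[1], p[2]] <- TRUE
    }
  }
  skel
}

# Length of an ordered pixel path. "chord" resamples the path with a fixed
# stride so staircase quantization does not bias the estimate (a pure
# (1, sqrt 2) step sum overestimates oblique curves by up to ~8%);
# "steps" is the classical step sum.
path_length_px <- function(path, method = c("chord", "steps"), stride = 5L) {
  method <- match.arg(method)
  n <- nrow(path)
  if (n < 2) return(0)
  if (method == "steps") {
    d <- abs(diff(path[, 1])) + abs(diff(path[, 2]))
    return(sum(ifelse(d == 2, sqrt(2), 1)))
  }
  idx <- unique(c(seq(1L, n, by = stride), n))
  if (length(idx) < 2) idx <- c(1L, n)
  sum(sqrt(diff(path[idx, 1])^2 + diff(path[idx, 2])^2))
}

#' Skeletonize a fiber mask and build its pruned skeleton graph
#'
#' Topological thinning (Zhang-Suen) to a 1-px 8-connected skeleton,
#' followed by iterative removal of terminal spurs shorter than
#' `prune_below` micrometres. Branch pixels that touch are merged into a
#' single branch node (thinning artifact clusters). Pure cycles (rings
#' without endpoints or branchpoints) are traced as closed paths.
#'
#' @param mask logical fiber mask.
#' @param pixel_size um/px.
#' @param prune_below spur-length pruning threshold in micrometres.
#' @param length_method "chord" (default; stride-resampled, isotropically
#'   accurate) or "steps" (orthogonal 1, diagonal sqrt 2).
#' @return object of class `skeleton_graph`: list with `skeleton`
#'   (logical raster), `nodes` (data.frame: id, type, r, c), `edges`
#'   (list of paths with from/to node ids and `length_um`),
#'   `n_endpoints`, `n_branchpoints`, `pixel_size`.
#' @export
skeletonize_and_prune <- function(mask, pixel_size, prune_below = 5,
                                  length_method = "chord") {
  stopifnot(pixel_size > 0)
  if (!any(mask)) {
    return(structure(list(skeleton = mask, nodes = data.frame(),
                          edges = list(), n_endpoints = 0L,
                          n_branchpoints = 0L, pixel_size = pixel_size),
                     class = "skeleton_graph"))
  }
  skel <- minimal_skeleton(thin_mask(mask))
  for (iter in 1:10) {
    g <- build_skeleton_graph(skel, pixel_size, length_method)
    spurs <- which(vapply(g$edges, function(e) {
      ends <- g$nodes$type[match(c(e$from, e$to), g$nodes$id)]
      e$length_um < prune_below && any(ends == "endpoint", na.rm = TRUE)
    }, TRUE))
    if (length(spurs) == 0) break
    for (ei in spurs) {
      e <- g$edges[[ei]]
      keep_node <- g$nodes$type[match(c(e$from, e$to), g$nodes$id)] == "branch"
      path <- e$path
      # keep pixels belonging to a branch node at either end
      drop <- rep(TRUE, nrow(path))
      node_px <- g$node_pixels
      for (k in seq_len(nrow(path))) {
        key <- paste(path[k, 1], path[k, 2])
        if (!is.null(node_px[[key]]) &&
            g$nodes$type[node_px[[key]]] == "branch") drop[k] <- FALSE
      }
      skel[path[drop, , drop = FALSE]] <- FALSE
    }
    skel <- minimal_skeleton(thin_mask(skel))
    if (!any(skel)) break
  }
  skel <- extend_ends(skel, mask)
  g <- build_skeleton_graph(skel, pixel_size, length_method)
  structure(list(skeleton = skel, nodes = g$nodes, edges = g$edges,
                 n_endpoints = sum(g$nodes$type == "endpoint"),
                 n_branchpoints = sum(g$nodes$type == "branch"),
                 pixel_size = pixel_size),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph>", sum(x$skeleton), "skeleton px,",
      x$n_endpoints, "endpoints,", x$n_branchpoints, "branchpoints,",
      length(x$edges), "edges\n")
  invisible(x)
}

# Build node components and traced edges from a 1-px skeleton.
build_skeleton_graph <- function(skel, pixel_size, length_method = "chord") {
  h <- nrow(skel); w <- ncol(skel)
  nn <- neighbor_count(skel)
  node_mask <- skel & nn != 2
  lab <- label_components(node_mask)
  nid <- max(lab)
  nodes <- data.frame(id = integer(0), type = character(0),
                      r = numeric(0), c = numeric(0))
  node_pixels <- list()   # "r c" -> node id
  if (nid > 0) {
    typ <- character(nid); rr <- numeric(nid); cc <- numeric(nid)
    for (i in seq_len(nid)) {
      px <- which(lab == i, arr.ind = TRUE)
      typ[i] <- if (any(nn[lab == i] >= 3)) "branch"
        else if (all(nn[lab == i] == 0)) "isolated" else "endpoint"
      rr[i] <- mean(px[, 1]); cc[i] <- mean(px[, 2])
      for (k in seq_len(nrow(px)))
        node_pixels[[paste(px[k, 1], px[k, 2])]] <- i
    }
    nodes <- data.frame(id = seq_len(nid), type = typ, r = rr, c = cc)
  }
  offs <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  neighbors_of <- function(r, c) {
    pts <- cbind(r + offs[, 1], c + offs[, 2])
    pts <- pts[pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w, ,
               drop = FALSE]
    pts[skel[pts], , drop = FALSE]
  }
  used <- matrix(FALSE, h, w)   # interior pixels consumed by a trace
  edges <- list()
  add_edge <- function(path, from, to) {
    edges[[length(edges) + 1L]] <<- list(
      path = path, from = from, to = to,
      length_um = path_length_px(path, length_method) * pixel_size)
  }
  seen_pairs <- character(0)
  if (nid > 0) {
    node_idx <- which(node_mask, arr.ind = TRUE)
    for (k in seq_len(nrow(node_idx))) {
      r <- node_idx[k, 1]; c <- node_idx[k, 2]
      me <- lab[r, c]
      nbs <- neighbors_of(r, c)
      for (q in seq_len(nrow(nbs))) {
        qr <- nbs[q, 1]; qc <- nbs[q, 2]
        if (node_mask[qr, qc]) {
          other <- lab[qr, qc]
          if (other != me) {
            key <- paste(min(me, other), max(me, other), min(r * w + c, qr * w + qc))
            if (!(key %in% seen_pairs)) {
              seen_pairs <- c(seen_pairs, key)
              if (me < other) add_edge(rbind(c(r, c), c(qr, qc)), me, other)
            }
          }
          next
        }
        if (used[qr, qc]) next
        # walk along interior pixels until the next node pixel
        path <- rbind(c(r, c), c(qr, qc))
        used[qr, qc] <- TRUE
        prev <- c(r, c); cur <- c(qr, qc)
        repeat {
          cand <- neighbors_of(cur[1], cur[2])
          cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), ,
                       drop = FALSE]
          # drop neighbors already on this path (tight turns)
          if (nrow(cand) > 1) {
            on_path <- paste(cand[, 1], cand[, 2]) %in%
              paste(path[, 1], path[, 2])
            if (any(!on_path)) cand <- cand[!on_path, , drop = FALSE]
          }
          if (nrow(cand) == 0) { add_edge(path, me, NA_integer_); break }
          node_hit <- node_mask[cand]
          if (any(node_hit)) {
            nxt <- cand[which(node_hit)[1], ]
            path <- rbind(path, nxt)
            add_edge(path, me, lab[nxt[1], nxt[2]])
            break
          }
          nxt <- cand[1, ]
          if (used[nxt[1], nxt[2]]) { add_edge(path, me, NA_integer_); break }
          path <- rbind(path, nxt)
          used[nxt[1], nxt[2]] <- TRUE
          prev <- cur; cur <- nxt
        }
      }
    }
  }
  # pure cycles: interior pixels never visited
  remaining <- which(skel & !used & !node_mask, arr.ind = TRUE)
  while (nrow(remaining) > 0) {
    start <- remaining[1, ]
    path <- matrix(start, 1, 2)
    used[start[1], start[2]] <- TRUE
    prev <- start; cur <- start
    repeat {
      cand <- neighbors_of(cur[1], cur[2])
      cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), ,
                   drop = FALSE]
      cand <- cand[!used[cand], , drop = FALSE]
      if (nrow(cand) == 0) break
      nxt <- cand[1, ]
      path <- rbind(path, nxt)
      used[nxt[1], nxt[2]] <- TRUE
      prev <- cur; cur <- nxt
    }
    path <- rbind(path, start)  # close the loop
    add_edge(path, NA_integer_, NA_integer_)
    remaining <- which(skel & !used & !node_mask, arr.ind = TRUE)
  }
  list(nodes = nodes, edges = edges, node_pixels = node_pixels)
}

# Otsu threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  h <- hist(x, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Compute the 13 fibrillary morphology metrics
#'
#' @param mask logical fibrillary-matrix mask.
#' @param skeleton a [skeletonize_and_prune()] result for `mask`.
#' @param intensity eosin-concentration raster (same dims) used for the
#'   high-density-matrix (HDM) fraction; may be NULL (HDM becomes NA).
#' @param roi_mask logical region-of-interest raster; defaults to the
#'   full frame.
#' @param pixel_size um/px.
#' @param curvature_window chord window for curvature, micrometres.
#' @param hdm_threshold absolute intensity threshold, or "otsu" to derive
#'   it from the ROI pixels.
#' @return one-row data.frame with the 13 metrics plus `mask_area`,
#'   `roi_area` and `n_edges`:
#'   `n_endpoints`, `n_branchpoints`, `endpoint_branchpoint_ratio`,
#'   `total_length` (um), `avg_fiber_length` (um), `hyphal_growth_unit`
#'   (um; total length / endpoints), `curvature` (mean |degrees| per chord
#'   step), `alignment` (structure-tensor coherence in `[0,1]`),
#'   `fractal_dimension`, `lacunarity` (gliding box, >= 1), `density`
#'   (mask fraction of ROI), `hdm` (high-intensity fraction of ROI),
#'   `mean_gap_diameter` (um).
#' @export
compute_metrics <- function(mask, skeleton, intensity = NULL,
                            roi_mask = NULL, pixel_size = 1,
                            curvature_window = 20,
                            hdm_threshold = "otsu") {
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  roi_area_um2 <- sum(roi_mask) * pixel_size^2
  stopifnot(roi_area_um2 > 0)
  mask <- mask & roi_mask
  n_end <- skeleton$n_endpoints
  n_branch <- skeleton$n_branchpoints
  lengths <- vapply(skeleton$edges, `[[`, 0, "length_um")
  total_len <- sum(lengths)
  n_edges <- length(lengths)
  avg_len <- if (n_edges > 0) total_len / n_edges else NA_real_
  hgu <- if (n_end > 0) total_len / n_end else NA_real_
  curv <- path_curvature(skeleton, curvature_window, pixel_size)
  align <- alignment_coherence(mask, roi_mask)
  bx <- box_metrics(mask, roi_mask)
  dens <- sum(mask) * pixel_size^2 / roi_area_um2
  hdm <- NA_real_
  if (!is.null(intensity)) {
    vals <- intensity[roi_mask]
    thr <- if (identical(hdm_threshold, "otsu")) otsu_threshold(vals)
      else hdm_threshold
    hdm <- mean(vals > thr)
  }
  gap <- mean_gap_diameter(mask, roi_mask, pixel_size)
  data.frame(
    n_endpoints = n_end, n_branchpoints = n_branch,
    endpoint_branchpoint_ratio = n_end / max(n_branch, 1),
    total_length = total_len, avg_fiber_length = avg_len,
    hyphal_growth_unit = hgu, curvature = curv, alignment = align,
    fractal_dimension = bx$fd, lacunarity = bx$lac, density = dens,
    hdm = hdm, mean_gap_diameter = gap,
    mask_area = sum(mask) * pixel_size^2, roi_area = roi_area_um2,
    n_edges = n_edges)
}

METRIC_COLUMNS <- c("n_endpoints", "n_branchpoints",
                    "endpoint_branchpoint_ratio", "total_length",
                    "avg_fiber_length", "hyphal_growth_unit", "curvature",
                    "alignment", "fractal_dimension", "lacunarity",
                    "density", "hdm", "mean_gap_diameter")

# mean absolute orientation change (degrees) between successive chords of
# a fixed physical window along every skeleton path
path_curvature <- function(skeleton, window_um, pixel_size) {
  k <- max(2L, round(window_um / pixel_size / 1.2))
  angs <- c()
  for (e in skeleton$edges) {
    p <- e$path
    idx <- seq(1L, nrow(p), by = k)
    if (length(idx) < 3) next
    dy <- diff(p[idx, 1]); dx <- diff(p[idx, 2])
    th <- atan2(dy, dx)
    dth <- diff(th)
    dth <- atan2(sin(dth), cos(dth))   # wrap to (-pi, pi]
    angs <- c(angs, abs(dth) * 180 / pi)
  }
  if (length(angs) == 0) return(0)
  mean(angs)
}

# structure-tensor coherence (lambda1 - lambda2)/(lambda1 + lambda2)
alignment_coherence <- function(mask, roi_mask, sigma = 2) {
  m <- gauss_smooth(mask * 1, sigma)
  gx <- fix_na_border(grad_x(m)); gy <- fix_na_border(grad_y(m))
  sel <- roi_mask
  jxx <- sum(gx[sel]^2); jyy <- sum(gy[sel]^2); jxy <- sum((gx * gy)[sel])
  tr <- jxx + jyy
  if (tr <= 0) return(0)
  sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr
}

# box-count fractal dimension and gliding-box lacunarity over dyadic boxes
box_metrics <- function(mask, roi_mask) {
  h <- nrow(mask); w <- ncol(mask)
  smax <- floor(min(h, w) / 4)
  sizes <- 2^(1:20)
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 2) sizes <- c(2L, 4L)[c(2L, 4L) <= min(h, w)]
  if (length(sizes) == 0) return(list(fd = NA_real_, lac = NA_real_))
  ii <- integral_image(mask * 1)
  counts <- numeric(length(sizes))
  lam <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    sums <- gliding_box_sums(ii, s)
    # non-overlapping grid for box counting
    rr <- seq(1L, nrow(sums), by = s); cc <- seq(1L, ncol(sums), by = s)
    counts[i] <- sum(sums[rr, cc, drop = FALSE] > 0)
    mu <- mean(sums); v <- stats::var(as.numeric(sums))
    lam[i] <- if (mu > 0) 1 + v / mu^2 else NA_real_
  }
  keep <- counts > 0
  fd <- if (sum(keep) >= 2)
    -stats::coef(stats::lm(log(counts[keep]) ~ log(sizes[keep])))[[2]]
  else NA_real_
  list(fd = fd, lac = mean(lam, na.rm = TRUE))
}

# 2 x mean of the local maxima of the distance transform of ROI \ mask
mean_gap_diameter <- function(mask, roi_mask, pixel_size) {
  gap_space <- roi_mask & !mask
  if (!any(gap_space)) return(0)
  if (!any(mask)) return(NA_real_)
  d <- distance_transform(mask)
  d[!gap_space] <- 0
  mx <- local_maxima(d, min_value = 0)
  vals <- d[mx & gap_space]
  if (length(vals) == 0) return(0)
  2 * mean(vals) * pixel_size
}
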