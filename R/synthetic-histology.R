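# Synthetic histology and cohort generator: calibrated IHC-like and
# H&E-like rasters, fiber networks with controllable morphology, and
# cohort tables with the statistical structure the analysis assumes
# (lesion random intercepts, TLS-stage and fiber-phenotype effects on TIL
# counts). Everything is seeded and carries ground truth for
# parameter-recovery tests.

# Fixed chromogen constants (RGB, 0..255): thresholds in
# chromogen_thresholds() are written against these hues.
CHROMOGEN_RGB <- list(
  brown = c(140, 90, 40),    # DAB-like (CD3 T cells)
  pink  = c(230, 105, 160),  # fast-red-like (CD20 B cells)
  blue  = c(70, 85, 160)     # hematoxylin-like counterstain
)

#' Fiber phenotype parameters
#'
#' Generative controls for a correlated-random-walk fiber network. Two
#' presets span the two fibrillary phenotypes the pipeline is designed to
#' separate: `"A"` — long, sparse, isotropic, gappy fibers (the
#' TIL-permissive morphology: high lacunarity and average length, low
#' density and alignment); `"B"` — short, dense, aligned, heavily
#' crosslinked fibers (high hyphal growth unit and density).
#'
#' @param n_fibers batch-size hint; generation continues until
#'   `target_coverage` is met.
#' @param mean_length mean fiber length, um.
#' @param length_cv coefficient of variation of fiber length.
#' @param orientation_kappa von Mises concentration of initial fiber
#'   orientations (0 = isotropic).
#' @param mean_direction mean fiber direction, radians.
#' @param step_angle_sd turning-angle SD in degrees per um of path
#'   (curvature driver).
#' @param branching_rate branches per 100 um of fiber.
#' @param crosslink_density junctions per 1000 um^2: this many fibers are
#'   seeded from points on already-drawn fibers.
#' @param fiber_width fiber width, um.
#' @param target_coverage fraction of the ROI the rasterized mask should
#'   cover, in `[0, 1)`.
#' @return object of class `fiber_phenotype_params`.
#' @export
fiber_phenotype_params <- function(n_fibers = 100, mean_length = 50,
                                   length_cv = 0.3, orientation_kappa = 0,
                                   mean_direction = 0, step_angle_sd = 2,
                                   branching_rate = 0.5,
                                   crosslink_density = 0, fiber_width = 2,
                                   target_coverage = 0.2) {
  p <- list(n_fibers = n_fibers, mean_length = mean_length,
            length_cv = length_cv, orientation_kappa = orientation_kappa,
            mean_direction = mean_direction, step_angle_sd = step_angle_sd,
            branching_rate = branching_rate,
            crosslink_density = crosslink_density,
            fiber_width = fiber_width, target_coverage = target_coverage)
  stopifnot(all(unlist(p[-5]) >= 0), target_coverage < 1,
            mean_length > fiber_width)
  structure(p, class = "fiber_phenotype_params")
}

#' @rdname fiber_phenotype_params
#' @param phenotype `"A"` or `"B"`.
#' @export
fiber_phenotype_preset <- function(phenotype = c("A", "B")) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "A")
    fiber_phenotype_params(n_fibers = 100, mean_length = 50,
                           length_cv = 0.3, orientation_kappa = 0.3,
                           step_angle_sd = 2, branching_rate = 0.2,
                           crosslink_density = 0.2, fiber_width = 2.4,
                           target_coverage = 0.18)
  else
    fiber_phenotype_params(n_fibers = 200, mean_length = 55,
                           length_cv = 0.3, orientation_kappa = 8,
                           step_angle_sd = 0.5, branching_rate = 2.5,
                           crosslink_density = 6, fiber_width = 5,
                           target_coverage = 0.36)
}

# von Mises sampler (Best & Fisher rejection); kappa = 0 is uniform.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  if (kappa > 1e5) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

#' Generate a synthetic fiber network
#'
#' Fibers are correlated random walks: initial orientation von Mises
#' around `mean_direction`, per-step turning angle Normal(0,
#' `step_angle_sd` x step). Branches fork off at `branching_rate` per
#' 100 um; `crosslink_density` fibers per 1000 um^2 are seeded from
#' points on already-drawn fibers (their proximal end is a junction, not
#' an endpoint). Drawing stops when the rasterized mask reaches
#' `target_coverage` (within 10% relative).
#'
#' @param params a [fiber_phenotype_params()].
#' @param roi_dim c(height, width) of the raster in px (>= 100 x 100).
#' @param pixel_size um/px.
#' @param seed integer seed; same seed and params give a bit-identical
#'   raster.
#' @return list with `mask` (logical raster), `polylines` (list of
#'   two-column matrices in um), `orientations` (initial angle per
#'   fiber), `coverage`.
#' @export
generate_fiber_network <- function(params, roi_dim, pixel_size = 1,
                                   seed = 1) {
  stopifnot(inherits(params, "fiber_phenotype_params"),
            all(roi_dim >= 100))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- roi_dim[1]; w <- roi_dim[2]
  mask <- matrix(FALSE, h, w)
  wr <- max(0.5, params$fiber_width / 2 / pixel_size)
  dk <- which(disk_kernel(wr) == 1, arr.ind = TRUE)
  dk <- cbind(dk[, 1] - (max(dk[, 1]) + 1) / 2, dk[, 2] - (max(dk[, 2]) + 1) / 2)
  polylines <- list()
  orientations <- numeric(0)
  centers_r <- numeric(0); centers_c <- numeric(0)
  n_cross_target <- round(params$crosslink_density * h * w *
                            pixel_size^2 / 1000)
  n_cross <- 0
  fibers <- 0
  max_fibers <- max(2000, 30 * params$n_fibers)
  pending <- list()   # branch seeds: list(r, c, theta)
  target <- params$target_coverage
  sdlog <- sqrt(log(1 + params$length_cv^2))
  while (sum(mask) / (h * w) < target) {
    if (fibers >= max_fibers)
      stop("target_coverage unreachable after ", fibers,
           " fibers; limiting parameter: mean_length or n_fibers too ",
           "small for target_coverage")
    if (length(pending) > 0) {
      seed_pt <- pending[[1]]; pending <- pending[-1]
      r0 <- seed_pt$r; c0 <- seed_pt$c; theta <- seed_pt$theta
      attached <- TRUE
    } else if (n_cross < n_cross_target && length(centers_r) > 0) {
      j <- sample.int(length(centers_r), 1)
      r0 <- centers_r[j]; c0 <- centers_c[j]
      theta <- rvonmises(1, params$mean_direction, params$orientation_kappa)
      n_cross <- n_cross + 1
      attached <- TRUE
    } else {
      r0 <- stats::runif(1, 1, h); c0 <- stats::runif(1, 1, w)
      theta <- rvonmises(1, params$mean_direction, params$orientation_kappa)
      attached <- FALSE
    }
    len_um <- stats::rlnorm(1, log(params$mean_length) - sdlog^2 / 2, sdlog)
    n_steps <- max(2L, ceiling(len_um / pixel_size))
    turns <- stats::rnorm(n_steps - 1, 0,
                          params$step_angle_sd * pixel_size) * pi / 180
    th <- theta + cumsum(c(0, turns))
    rr <- r0 + cumsum(c(0, sin(th[-1])))
    cc <- c0 + cumsum(c(0, cos(th[-1])))
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (any(!keep)) {
      cut <- which(!keep)[1] - 1L
      if (cut < 2) { fibers <- fibers + 1; next }
      rr <- rr[1:cut]; cc <- cc[1:cut]; th <- th[1:cut]
    }
    pr <- round(rr); pc <- round(cc)
    # paint thick line: every path pixel plus disk offsets
    ar <- rep(pr, each = nrow(dk)) + dk[, 1]
    ac <- rep(pc, each = nrow(dk)) + dk[, 2]
    ok <- ar >= 1 & ar <= h & ac >= 1 & ac <= w
    mask[cbind(ar[ok], ac[ok])] <- TRUE
    centers_r <- c(centers_r, rr); centers_c <- c(centers_c, cc)
    polylines[[length(polylines) + 1L]] <-
      cbind(x_um = (cc - 0.5) * pixel_size, y_um = (rr - 0.5) * pixel_size)
    orientations <- c(orientations, theta)
    fibers <- fibers + 1
    # branch seeds along this fiber
    p_branch <- params$branching_rate * pixel_size / 100
    if (p_branch > 0 && length(rr) > 2) {
      at <- which(stats::runif(length(rr) - 2) < p_branch) + 1L
      for (k in at)
        pending[[length(pending) + 1L]] <-
          list(r = rr[k], c = cc[k],
               theta = th[k] + sample(c(-1, 1), 1) * stats::rnorm(1, pi / 6, pi / 18))
    }
  }
  list(mask = mask, polylines = polylines, orientations = orientations,
       coverage = sum(mask) / (h * w))
}

#' Render a dual-chromogen IHC-like image
#'
#' White background; T cells drawn as brown disks, B cells pink, nuclei
#' blue, with slight per-cell color jitter. Cells are planted per region
#' with region precedence tumor > TLS > stroma: a cell center falling
#' inside a higher-precedence region is resampled (and the conflict
#' counted).
#'
#' @param regions a [region_set()].
#' @param densities named list region id -> list(t =, b =, nuclei =)
#'   absolute cell counts to plant.
#' @param dims c(height, width) of the raster.
#' @param pixel_size um/px.
#' @param seed integer seed.
#' @param cell_radius_um lymphocyte radius (default 3.5).
#' @return list with `image` (h x w x 3), `truth` (data.frame id,
#'   t_planted, b_planted), `conflicts` count.
#' @export
render_ihc <- function(regions, densities, dims, pixel_size = 1, seed = 1,
                       cell_radius_um = 3.5) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- dims[1]; w <- dims[2]
  img <- array(255, dim = c(h, w, 3))
  prec <- c(tumor = 1, tls = 2, stroma = 3, control_fov = 4, tissue = 5)
  regs <- regions$regions
  ord <- order(prec[vapply(regs, `[[`, "", "role")])
  truth <- list(); conflicts <- 0
  higher <- list()
  for (i in ord) {
    rg <- regs[[i]]
    dd <- densities[[rg$id]]
    if (is.null(dd)) dd <- list(t = 0, b = 0, nuclei = 0)
    stopifnot(all(unlist(dd) >= 0))
    plant <- function(n, color, radius_um) {
      placed <- 0; tries <- 0
      while (placed < n && tries < 50) {
        pts <- sample_in_poly(n - placed, rg$poly)
        if (length(higher) > 0) {
          clash <- Reduce(`|`, lapply(higher, function(hp)
            point_in_poly(pts[, 1], pts[, 2], hp)))
          conflicts <<- conflicts + sum(clash)
          pts <- pts[!clash, , drop = FALSE]
        }
        for (k in seq_len(nrow(pts)))
          img <<- paint_disk(img, pts[k, 2], pts[k, 1],
                             radius_um / pixel_size, color)
        placed <- placed + nrow(pts)
        tries <- tries + 1
      }
      placed
    }
    nk <- plant(dd$nuclei %||% 0, CHROMOGEN_RGB$blue, 2.5)
    tp <- plant(dd$t %||% 0, CHROMOGEN_RGB$brown, cell_radius_um)
    bp <- plant(dd$b %||% 0, CHROMOGEN_RGB$pink, cell_radius_um)
    truth[[length(truth) + 1L]] <-
      data.frame(id = rg$id, role = rg$role, t_planted = tp, b_planted = bp,
                 nuclei_planted = nk)
    higher[[length(higher) + 1L]] <- rg$poly
  }
  list(image = img, truth = do.call(rbind, truth), conflicts = conflicts)
}

# stamp a jittered solid disk onto an RGB canvas (row = y)
paint_disk <- function(img, r, c, radius_px, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  dk <- which(disk_kernel(radius_px) == 1, arr.ind = TRUE)
  ctr <- (max(dk[, 1]) + 1) / 2
  rr <- round(r) + dk[, 1] - ctr; cc <- round(c) + dk[, 2] - ctr
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  rr <- rr[ok]; cc <- cc[ok]
  jit <- stats::rnorm(3, 0, 5)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cbind(rr, cc)] <- max(0, min(255, color[ch] + jit[ch]))
    img[, , ch] <- plane
  }
  img
}

#' Render an H&E-like image and truth masks for one stromal scene
#'
#' Composes an eosin concentration map (fibrillary network, optional
#' mucin blobs, faint stromal background), a hematoxylin map (nuclei
#' disks), converts to RGB through the Beer-Lambert forward model, and
#' returns per-class truth masks.
#'
#' @param fiber a [generate_fiber_network()] result (or NULL).
#' @param dims c(h, w).
#' @param pixel_size um/px.
#' @param seed integer seed.
#' @param n_nuclei,n_mucin_blobs scene content.
#' @param noise_sd additive OD noise.
#' @return list with `image_he`, `eosin_truth`, `truth` (list of logical
#'   masks: fibrillary, nuclei, mucin, background), `pixel_size`.
#' @export
render_he_scene <- function(fiber = NULL, dims = c(256, 256),
                            pixel_size = 1, seed = 1, n_nuclei = 60,
                            n_mucin_blobs = 3, noise_sd = 0.01) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- dims[1]; w <- dims[2]
  fib_mask <- if (is.null(fiber)) matrix(FALSE, h, w) else fiber$mask
  mucin <- matrix(FALSE, h, w)
  if (n_mucin_blobs > 0) {
    seeds <- matrix(FALSE, h, w)
    seeds[cbind(sample.int(h, n_mucin_blobs), sample.int(w, n_mucin_blobs))] <- TRUE
    mucin <- dilate_disk(seeds, 18 / pixel_size) & !fib_mask
  }
  nuc <- matrix(FALSE, h, w)
  if (n_nuclei > 0) {
    ctrs <- cbind(sample.int(h, n_nuclei, replace = TRUE),
                  sample.int(w, n_nuclei, replace = TRUE))
    seeds <- matrix(FALSE, h, w); seeds[ctrs] <- TRUE
    nuc <- dilate_disk(seeds, 3 / pixel_size)
  }
  eosin <- matrix(0.10, h, w)
  eosin[mucin] <- 0.45
  eosin[fib_mask] <- 1.1
  eosin <- gauss_smooth(eosin, 0.8)
  hema <- matrix(0.04, h, w)
  hema[nuc] <- 1.0
  hema <- gauss_smooth(hema, 0.8)
  M <- stain_matrix(c("hematoxylin", "eosin"))
  od <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    od[, , ch] <- hema * M[1, ch] + eosin * M[2, ch] +
      stats::rnorm(h * w, 0, noise_sd)
  od[od < 0] <- 0
  img <- od_to_rgb(od)
  background <- !(fib_mask | mucin | nuc)
  list(image_he = img, eosin_truth = eosin,
       truth = list(fibrillary = fib_mask & !nuc, nuclei = nuc,
                    mucin = mucin & !nuc, background = background),
       pixel_size = pixel_size)
}

#' Cohort generation parameters
#'
#' Defaults encode the cohort structure the package's analyses assume:
#' covariate frequencies near the 30-lesion cohort (nodular 0.83,
#' superficial 0.33, infiltrative 0.17, ulceration 0.70), a
#' nodular-component enrichment of TLS presence with log-odds
#' `log(10.29)`, a TIL count model with log-scale primary-TLS effect 0.7
#' and fiber-phenotype-A effect 0.8 over a lesion random intercept
#' (SD 0.5), gamma-Poisson overdispersion, and a tumor-killing
#' probability increasing in log TIL count.
#'
#' @param n_lesions number of lesions (>= 2).
#' @param p_nodular,p_superficial,p_infiltrative,p_ulceration subtype /
#'   ulceration probabilities.
#' @param tls_logit_intercept,tls_logit_nodular log-odds of TLS presence.
#' @param stage_logit log-odds a TLS is primary (vs aggregate).
#' @param til_beta0 log baseline mean TIL count.
#' @param til_beta_primary,til_beta_phenotypeA log-scale effects.
#' @param lesion_sd SD of the lesion random intercept.
#' @param til_dispersion negative-binomial size (smaller = more
#'   overdispersed).
#' @param killing_logit_intercept,killing_logit_slope killing model
#'   (slope per log TIL).
#' @param tumors_per_tls_mean,tls_per_lesion_mean,controls_mean Poisson
#'   means for cohort layout.
#' @param seed integer seed.
#' @return object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_lesions = 30, p_nodular = 0.83,
                              p_superficial = 0.33, p_infiltrative = 0.17,
                              p_ulceration = 0.70,
                              tls_logit_intercept = -1.386,
                              tls_logit_nodular = log(10.29),
                              stage_logit = -1.1, til_beta0 = 3.0,
                              til_beta_primary = 0.7,
                              til_beta_phenotypeA = 0.8, lesion_sd = 0.5,
                              til_dispersion = 3,
                              killing_logit_intercept = -4,
                              killing_logit_slope = 1.0,
                              tumors_per_tls_mean = 2,
                              tls_per_lesion_mean = 1.5,
                              controls_mean = 1, seed = 1) {
  p <- as.list(environment())
  stopifnot(all(unlist(p[c("p_nodular", "p_superficial", "p_infiltrative",
                           "p_ulceration")]) >= 0),
            all(unlist(p[c("p_nodular", "p_superficial", "p_infiltrative",
                           "p_ulceration")]) <= 1),
            lesion_sd >= 0, til_dispersion > 0)
  structure(p, class = "cohort_gen_params")
}

draw_lesions <- function(params) {
  n <- params$n_lesions
  lesions <- data.frame(
    lesion_id = sprintf("L%03d", seq_len(n)),
    nodular = stats::rbinom(n, 1, params$p_nodular),
    superficial = stats::rbinom(n, 1, params$p_superficial),
    infiltrative = stats::rbinom(n, 1, params$p_infiltrative),
    ulceration = stats::rbinom(n, 1, params$p_ulceration),
    age = round(stats::runif(n, 43, 90)),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
    body_site = sample(c("head_neck", "trunk", "extremity"), n,
                       replace = TRUE, prob = c(0.53, 0.37, 0.10)))
  lesions$b_lesion <- stats::rnorm(n, 0, params$lesion_sd)
  lesions$any_tls <- stats::rbinom(n, 1, stats::plogis(
    params$tls_logit_intercept + params$tls_logit_nodular * lesions$nodular))
  lesions
}

#' Generate only the lesion-level table of a synthetic cohort
#'
#' Fast path for large-n checks of the lesion covariate and TLS-presence
#' model (identical draws to [generate_cohort()]'s lesion stage).
#'
#' @param params a [cohort_gen_params()].
#' @return lesions data.frame.
#' @export
generate_cohort_lesions <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  if (params$n_lesions < 2) stop("need at least 2 lesions")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  draw_lesions(params)
}

#' Generate a synthetic cohort (tables + ground truth)
#'
#' Lesion covariates are independent Bernoulli draws; TLS presence is
#' logistic in the nodular flag; each TLS is primary with probability
#' `plogis(stage_logit)`; per-tumor TIL counts are gamma-Poisson
#' (negative binomial) with log-mean `til_beta0 + til_beta_primary *
#' primary + til_beta_phenotypeA * phenotypeA + b_lesion`,
#' `b_lesion ~ N(0, lesion_sd^2)`; killing is Bernoulli in log TIL count.
#' TLS-level T/B counts and areas are drawn lognormally around
#' stage-conditional medians so primary TLS are larger and more B-rich.
#'
#' @param params a [cohort_gen_params()].
#' @return list of data.frames `lesions`, `tls`, `tumors`, plus `params`.
#' @export
generate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  if (params$n_lesions < 2) stop("need at least 2 lesions")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  n <- params$n_lesions
  lesions <- draw_lesions(params)
  tls_rows <- list(); tumor_rows <- list()
  stage_medians <- list(
    aggregate = list(b = exp(1.4), total = exp(6.1), area = 0.06),
    primary   = list(b = exp(3.8), total = exp(7.2), area = 0.155))
  for (i in seq_len(n)) {
    if (lesions$any_tls[i] == 1) {
      n_tls <- 1 + stats::rpois(1, params$tls_per_lesion_mean)
      for (t in seq_len(n_tls)) {
        primary <- stats::rbinom(1, 1, stats::plogis(params$stage_logit))
        stage <- if (primary == 1) "primary" else "aggregate"
        med <- stage_medians[[stage]]
        b_count <- round(stats::rlnorm(1, log(med$b), 0.8))
        total <- round(stats::rlnorm(1, log(med$total), 0.6))
        tls_id <- sprintf("%s_TLS%d", lesions$lesion_id[i], t)
        tls_rows[[length(tls_rows) + 1L]] <- data.frame(
          lesion_id = lesions$lesion_id[i], tls_id = tls_id, stage = stage,
          t_count = max(total - b_count, 0), b_count = b_count,
          area_mm2 = stats::rlnorm(1, log(med$area), 0.5))
        n_tum <- 1 + stats::rpois(1, params$tumors_per_tls_mean)
        for (u in seq_len(n_tum)) {
          phenoA <- stats::rbinom(1, 1, 0.5)
          mu <- exp(params$til_beta0 + params$til_beta_primary * primary +
                    params$til_beta_phenotypeA * phenoA + lesions$b_lesion[i])
          til <- stats::rnbinom(1, size = params$til_dispersion, mu = mu)
          tumor_rows[[length(tumor_rows) + 1L]] <- data.frame(
            lesion_id = lesions$lesion_id[i],
            tumor_id = sprintf("%s_T%d", tls_id, u), tls_id = tls_id,
            proximity = "proximal", stage = stage, phenotype = if (phenoA == 1) "A" else "B",
            til_count = til)
        }
      }
    } else {
      n_ctl <- 1 + stats::rpois(1, params$controls_mean)
      for (u in seq_len(n_ctl)) {
        phenoA <- stats::rbinom(1, 1, 0.5)
        mu <- exp(params$til_beta0 + params$til_beta_phenotypeA * phenoA +
                  lesions$b_lesion[i])
        til <- stats::rnbinom(1, size = params$til_dispersion, mu = mu)
        tumor_rows[[length(tumor_rows) + 1L]] <- data.frame(
          lesion_id = lesions$lesion_id[i],
          tumor_id = sprintf("%s_C%d", lesions$lesion_id[i], u),
          tls_id = NA_character_, proximity = "control", stage = "none",
          phenotype = if (phenoA == 1) "A" else "B", til_count = til)
      }
    }
  }
  tumors <- do.call(rbind, tumor_rows)
  tumors$killing <- stats::rbinom(nrow(tumors), 1, stats::plogis(
    params$killing_logit_intercept +
      params$killing_logit_slope * log(tumors$til_count + 1)))
  list(lesions = lesions,
       tls = if (length(tls_rows)) do.call(rbind, tls_rows) else NULL,
       tumors = tumors, params = params)
}

#' Simulate a two-phenotype fibrillary cohort with linked TIL counts
#'
#' For each stromal region: a fiber network drawn from phenotype A or B
#' preset parameters, measured with the package's own morphometrics, and
#' a TIL count drawn from the cohort count model (phenotype-A log effect
#' from `cohort`). This is the desk-scale stand-in for the
#' metrics-vs-TILs analyses.
#'
#' @param n_regions number of stromal regions (half A, half B).
#' @param roi_px side of the square ROI in px.
#' @param pixel_size um/px.
#' @param seed integer seed.
#' @param cohort a [cohort_gen_params()] for the TIL model.
#' @param params_A,params_B phenotype presets (defaults
#'   [fiber_phenotype_preset()]).
#' @return data.frame: one row per region with the 13 metrics,
#'   `phenotype`, `til_count`, `lesion_id`.
#' @export
simulate_phenotype_cohort <- function(n_regions = 60, roi_px = 200,
                                      pixel_size = 1, seed = 1,
                                      cohort = cohort_gen_params(),
                                      params_A = fiber_phenotype_preset("A"),
                                      params_B = fiber_phenotype_preset("B")) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  phen <- rep(c("A", "B"), length.out = n_regions)
  rows <- vector("list", n_regions)
  set.seed(seed)
  lesion_of <- rep(seq_len(max(2, ceiling(n_regions / 4))),
                   length.out = n_regions)
  b_lesion <- stats::rnorm(max(lesion_of), 0, cohort$lesion_sd)
  til_seeds <- stats::rnbinom(n_regions, size = cohort$til_dispersion,
    mu = exp(cohort$til_beta0 +
             cohort$til_beta_phenotypeA * (phen == "A") +
             b_lesion[lesion_of]))
  for (i in seq_len(n_regions)) {
    pp <- if (phen[i] == "A") params_A else params_B
    net <- generate_fiber_network(pp, c(roi_px, roi_px), pixel_size,
                                  seed = seed + 1000 + i)
    sk <- skeletonize_and_prune(net$mask, pixel_size)
    met <- compute_metrics(net$mask, sk,
                           intensity = gauss_smooth(net$mask * 1, 1.5),
                           pixel_size = pixel_size, hdm_threshold = 0.25)
    met$phenotype <- phen[i]
    met$til_count <- til_seeds[i]
    met$lesion_id <- sprintf("L%03d", lesion_of[i])
    rows[[i]] <- met
  }
  do.call(rbind, rows)
}
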