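# Beer-Lambert stain separation: RGB -> optical density -> per-stain
# concentration rasters by inverting a matrix of stain OD vectors.

# Published OD triplets (Ruifrok & Johnston style constants), unit-norm
# after construction; overridable by the user.
STAIN_OD <- list(
  hematoxylin = c(0.650, 0.704, 0.286),
  eosin       = c(0.072, 0.990, 0.105),
  dab         = c(0.268, 0.570, 0.776)
)

#' Build a stain matrix
#'
#' Stain vectors are unit 2-norm, nonnegative optical-density triplets, one
#' per stain. When only two stains are given the third is the unit residual
#' orthogonal to both (componentwise absolute value, renormalized).
#'
#' @param stains named list of length-3 numeric OD vectors, or a character
#'   vector naming built-ins (`"hematoxylin"`, `"eosin"`, `"dab"`).
#' @return object of class `stain_matrix`: 3x3 matrix, rows = stains.
#' @export
stain_matrix <- function(stains = c("hematoxylin", "eosin")) {
  if (is.character(stains)) {
    miss <- setdiff(stains, names(STAIN_OD))
    if (length(miss) > 0) stop("unknown stain(s): ", paste(miss, collapse = ", "))
    stains <- STAIN_OD[stains]
  }
  stopifnot(length(stains) %in% c(2, 3))
  M <- do.call(rbind, lapply(stains, function(v) {
    stopifnot(length(v) == 3, all(v >= 0))
    v / sqrt(sum(v^2))
  }))
  if (nrow(M) == 2) {
    resid <- abs(pracma_cross(M[1, ], M[2, ]))
    M <- rbind(M, residual = resid / sqrt(sum(resid^2)))
  }
  kappa <- kappa(M, exact = TRUE)
  if (!is.finite(kappa)) stop("stain matrix is singular")
  if (kappa > 1e3)
    warning("stain matrix badly conditioned (condition number ", round(kappa), ")")
  structure(M, class = c("stain_matrix", "matrix"))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' RGB raster to optical density
#'
#' OD = -log10((I + 1) / white_level) per channel, clamped at 0; the +1
#' avoids log(0) on fully saturated dark pixels.
#'
#' @param img h x w x 3 array of intensities in `[0, white_level]`.
#' @param white_level intensity of unstained background (default 255).
#' @return h x w x 3 array of optical densities.
#' @export
rgb_to_od <- function(img, white_level = 255) {
  stopifnot(white_level > 0, length(dim(img)) == 3)
  od <- -log10((img + 1) / white_level)
  od[od < 0] <- 0
  od
}

#' Optical density back to RGB
#' @param od OD array as produced by [rgb_to_od()].
#' @param white_level background intensity.
#' @return RGB intensity array.
#' @export
od_to_rgb <- function(od, white_level = 255) {
  out <- pmax(0, pmin(white_level, white_level * 10^(-od) - 1))
  if (!is.null(dim(od))) dim(out) <- dim(od)   # pmin/pmax drop dims
  out
}

#' Deconvolve an OD raster into per-stain concentrations
#'
#' Applies the inverse stain matrix per pixel. Negative concentrations
#' (noise, out-of-dictionary color) are clamped to zero and the clamped
#' fraction reported.
#'
#' @param od h x w x 3 optical-density array.
#' @param stains a [stain_matrix()].
#' @return list with `concentrations` (h x w x 3 array, dimnames on the
#'   stain axis), and `fraction_clamped`.
#' @export
deconvolve <- function(od, stains) {
  stopifnot(inherits(stains, "stain_matrix"))
  M <- unclass(stains)
  inv <- tryCatch(solve(t(M)), error = function(e) stop("singular stain matrix"))
  h <- dim(od)[1]; w <- dim(od)[2]
  flat <- matrix(od, h * w, 3)           # pixels x channels
  conc <- flat %*% t(inv)                # pixels x stains
  clamped <- mean(conc < -1e-12)
  conc[conc < 0] <- 0
  arr <- array(conc, dim = c(h, w, 3),
               dimnames = list(NULL, NULL, rownames(M)))
  list(concentrations = arr, fraction_clamped = clamped)
}

#' Extract one stain channel as a matrix
#' @param dec result of [deconvolve()].
#' @param stain stain name.
#' @export
stain_channel <- function(dec, stain) {
  stopifnot(stain %in% dimnames(dec$concentrations)[[3]])
  dec$concentrations[, , stain]
}
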