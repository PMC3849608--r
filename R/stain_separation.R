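#' Stain vectors for colour deconvolution
#'
#' Builds the 3-stain optical-density basis used to unmix a brightfield
#' RGB image into DAB and hematoxylin channels. The defaults are the
#' published H-DAB vectors of Ruifrok & Johnston; the third basis vector
#' is the normalized cross product of the two stains, which completes an
#' invertible basis without assuming a third chromogen.
#'
#' @param dab length-3 numeric, DAB optical-density vector (need not be
#'   normalized).
#' @param hematoxylin length-3 numeric, hematoxylin optical-density vector.
#' @return An object of class `stain_vectors`: a list with unit vectors
#'   `dab`, `hematoxylin`, `residual` and the 3x3 matrix `M` whose columns
#'   are (dab, hematoxylin, residual).
#' @examples
#' sv <- stain_vectors()
#' crossprod(sv$M) # near-identity off the residual column
#' @export
stain_vectors <- function(dab = c(0.269, 0.568, 0.778),
                          hematoxylin = c(0.650, 0.704, 0.286)) {
  dab <- as.numeric(dab)
  hem <- as.numeric(hematoxylin)
  if (length(dab) != 3L || length(hem) != 3L)
    stop("stain vectors must have length 3")
  if (any(!is.finite(dab)) || any(!is.finite(hem)))
    stop("stain vectors must be finite")
  nd <- sqrt(sum(dab^2)); nh <- sqrt(sum(hem^2))
  if (nd == 0 || nh == 0) stop("stain vectors must be non-zero")
  dab <- dab / nd
  hem <- hem / nh
  res <- c(dab[2] * hem[3] - dab[3] * hem[2],
           dab[3] * hem[1] - dab[1] * hem[3],
           dab[1] * hem[2] - dab[2] * hem[1])
  nr <- sqrt(sum(res^2))
  if (nr < 1e-9)
    stop("singular stain matrix: dab and hematoxylin vectors are collinear")
  res <- res / nr
  M <- cbind(dab = dab, hematoxylin = hem, residual = res)
  structure(list(dab = dab, hematoxylin = hem, residual = res, M = M),
            class = "stain_vectors")
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert relation channel-wise:
#' `od = -log10(max(pixel, 1) / background_level)`. Pixels brighter than
#' the background clamp to zero absorbance.
#'
#' @param img H x W x 3 array of integer intensities in \[0, 255\]
#'   (numeric arrays are accepted and rounded).
#' @param background_level scalar white level in \[1, 255\], or
#'   `"auto"` to use the per-image 99th-percentile intensity.
#' @return H x W x 3 numeric array of optical densities (>= 0).
#' @examples
#' px <- array(c(255, 0, 128), c(1, 1, 3))
#' rgb_to_od(px) # 0, log10(255), -log10(128/255) per channel
#' @export
rgb_to_od <- function(img, background_level = 255) {
  img <- check_rgb(img)
  if (identical(background_level, "auto")) {
    background_level <- max(1, stats::quantile(img, 0.99, names = FALSE))
  }
  if (!is.numeric(background_level) || length(background_level) != 1L ||
      background_level < 1 || background_level > 255)
    stop("background_level must be a scalar in [1, 255] or \"auto\"")
  od <- -log10(pmax(img, 1) / background_level)
  od[od < 0] <- 0
  od
}

#' Unmix an optical-density image into stain channels
#'
#' Solves the per-pixel 3x3 linear system `od = M %*% conc` for the stain
#' concentrations and returns the DAB and hematoxylin channels, clamped
#' at zero (negative unmixing results are not physical).
#'
#' @param od H x W x 3 optical-density array from [rgb_to_od()].
#' @param vectors a [stain_vectors()] object.
#' @return An object of class `stain_channels`: list with H x W matrices
#'   `dab_od` and `hem_od` (both >= 0) and the `vectors` used.
#' @export
deconvolve <- function(od, vectors = stain_vectors()) {
  if (!inherits(vectors, "stain_vectors")) stop("vectors must be stain_vectors")
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop("od must be a non-empty H x W x 3 array")
  Minv <- tryCatch(solve(vectors$M), error = function(e)
    stop("singular stain matrix: dab and hematoxylin vectors are collinear"))
  # pixels in rows: (H*W) x 3, concentrations = od %*% t(Minv)
  odm <- matrix(od, ncol = 3L)
  conc <- odm %*% t(Minv)
  dab <- matrix(pmax(conc[, 1L], 0), d[1], d[2])
  hem <- matrix(pmax(conc[, 2L], 0), d[1], d[2])
  structure(list(dab_od = dab, hem_od = hem, vectors = vectors),
            class = "stain_channels")
}

#' Synthesize an RGB image from stain concentration maps
#'
#' Inverse of the deconvolution: given per-pixel DAB and hematoxylin
#' concentrations, composes the optical density `a*V_dab + b*V_hem`,
#' optionally adds Gaussian noise in OD space, and converts back to 8-bit
#' RGB through the Beer-Lambert relation. Used by the synthetic tile
#' generator and by round-trip tests.
#'
#' @param dab_conc,hem_conc H x W numeric matrices of stain concentrations.
#' @param vectors a [stain_vectors()] object.
#' @param background_level white level (default 255).
#' @param noise_sigma Gaussian noise s.d. added per OD channel (default 0).
#' @param quantize round and clamp to integers in \[0, 255\] (default TRUE).
#' @return H x W x 3 array (integer-valued when `quantize`).
#' @export
synthesize_rgb <- function(dab_conc, hem_conc, vectors = stain_vectors(),
                           background_level = 255, noise_sigma = 0,
                           quantize = TRUE) {
  if (!identical(dim(dab_conc), dim(hem_conc)))
    stop("concentration maps must have the same shape")
  h <- nrow(dab_conc); w <- ncol(dab_conc)
  od <- array(0, c(h, w, 3L))
  for (k in 1:3)
    od[, , k] <- dab_conc * vectors$dab[k] + hem_conc * vectors$hematoxylin[k]
  if (noise_sigma > 0)
    od <- od + stats::rnorm(length(od), sd = noise_sigma)
  px <- background_level * 10^-od
  if (quantize) {
    px <- round(px)
    px[px < 0] <- 0
    px[px > 255] <- 255
  }
  px
}

# validate and coerce an RGB image array
check_rgb <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop("empty image")
  if (any(img < 0 | img > 255, na.rm = TRUE))
    stop("channel values must lie in [0, 255]")
  if (anyNA(img)) stop("image contains NA values")
  round(img)
}
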