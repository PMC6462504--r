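#' Camera and optics model
#'
#' Calibration of the detection path: count offset, inverse gain (photons
#' per count), Gaussian read noise, pixel size and nominal PSF width.
#' Conversion between camera counts and photons follows
#' `photons = (counts - offset) * inverse_gain`.
#'
#' Coordinates: positions are continuous, in micrometers, with the origin at
#' the top-left corner of the image; pixel `(row i, col j)` covers the
#' half-open square `[(i-1)*pixel_size, i*pixel_size) x
#' [(j-1)*pixel_size, j*pixel_size)` with y along rows and x along columns.
#'
#' @param offset count offset added by the camera (counts).
#' @param inverse_gain photons per count (> 0).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param pixel_size pixel edge in the sample plane (micrometers).
#' @param psf_sigma Gaussian PSF standard deviation (micrometers).
#' @param field_of_view image size as `c(rows, cols)` in pixels.
#' @param saturation full-well count value; pixels at or above it are
#'   flagged as saturated by [counts_to_photons()].
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(offset = 100, inverse_gain = 2, read_noise_sd = 1,
                         pixel_size = 0.16, psf_sigma = 0.2,
                         field_of_view = c(64L, 64L), saturation = 65535) {
  stopifnot(inverse_gain > 0, pixel_size > 0, psf_sigma > 0,
            read_noise_sd >= 0, length(field_of_view) == 2,
            all(field_of_view >= 4))
  structure(
    list(offset = offset, inverse_gain = inverse_gain,
         read_noise_sd = read_noise_sd, pixel_size = pixel_size,
         psf_sigma = psf_sigma,
         field_of_view = as.integer(field_of_view),
         saturation = saturation),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> offset %g counts, inverse gain %g ph/count, read noise %g counts\n  %d x %d px @ %.3g um/px, PSF sigma %.3g um\n",
    x$offset, x$inverse_gain, x$read_noise_sd,
    x$field_of_view[1], x$field_of_view[2], x$pixel_size, x$psf_sigma))
  invisible(x)
}

#' Convert a count image to photons
#'
#' Subtracts the camera offset and multiplies by the inverse gain. Negative
#' results (read-noise excursions below the offset) are clipped at zero and
#' the clipped fraction is reported; saturated pixels are flagged, never
#' silently used.
#'
#' @param image matrix of camera counts.
#' @param camera a [camera_model()].
#' @param clip clip negative photon values at zero (default TRUE). Use
#'   `clip = FALSE` for integrating estimators (e.g. surface density),
#'   where clipping read-noise excursions would bias the total upward.
#' @return A photon matrix with attributes `clipped_fraction` (fraction of
#'   pixels clipped at 0, or that would have been) and `saturated` (index
#'   vector of saturated pixels, possibly empty).
#' @export
counts_to_photons <- function(image, camera, clip = TRUE) {
  stopifnot(is.matrix(image), inherits(camera, "camera_model"))
  sat <- which(image >= camera$saturation)
  ph <- (image - camera$offset) * camera$inverse_gain
  clipped <- mean(ph < 0)
  if (clip) ph <- pmax(ph, 0)
  attr(ph, "clipped_fraction") <- clipped
  attr(ph, "saturated") <- sat
  ph
}

# Expected photon image from point emitters with an integrated Gaussian PSF.
# emitters: data.frame with x, y (um) and photons (expected photons/frame).
render_photon_field <- function(emitters, camera, background_photons = 0) {
  ny <- camera$field_of_view[1]
  nx <- camera$field_of_view[2]
  px <- camera$pixel_size
  s <- camera$psf_sigma
  mu <- matrix(background_photons, ny, nx)
  if (nrow(emitters) == 0) return(mu)
  half <- ceiling(4 * s / px)
  for (k in seq_len(nrow(emitters))) {
    x <- emitters$x[k]; y <- emitters$y[k]; b <- emitters$photons[k]
    ic <- floor(y / px) + 1  # row
    jc <- floor(x / px) + 1  # col
    i1 <- max(1L, ic - half); i2 <- min(ny, ic + half)
    j1 <- max(1L, jc - half); j2 <- min(nx, jc + half)
    if (i1 > i2 || j1 > j2) next
    ii <- i1:i2
    jj <- j1:j2
    wr <- stats::pnorm(ii * px, y, s) - stats::pnorm((ii - 1) * px, y, s)
    wc <- stats::pnorm(jj * px, x, s) - stats::pnorm((jj - 1) * px, x, s)
    mu[ii, jj] <- mu[ii, jj] + b * outer(wr, wc)
  }
  mu
}

#' Render a camera frame from point emitters
#'
#' Places each emitter's expected photons on the pixel grid through an
#' integrated 2-D Gaussian PSF, then applies the camera model: Poisson shot
#' noise on photons, division by the inverse gain, the count offset and
#' Gaussian read noise. With `noise = FALSE` the expectation image is
#' returned (no shot or read noise), which is useful for fixtures.
#'
#' @param emitters data.frame with columns `x`, `y` (micrometers) and
#'   `photons` (expected photons per frame per emitter).
#' @param camera a [camera_model()].
#' @param background_photons expected background photons per pixel.
#' @param noise simulate shot + read noise? (default TRUE)
#' @param seed optional integer seed.
#' @return Matrix of camera counts, `field_of_view[1]` x `field_of_view[2]`.
#' @export
render_frame <- function(emitters, camera, background_photons = 0,
                         noise = TRUE, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  mu <- render_photon_field(emitters, camera, background_photons)
  if (noise) {
    ph <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    counts <- camera$offset + ph / camera$inverse_gain +
      matrix(stats::rnorm(length(mu), 0, camera$read_noise_sd), nrow(mu), ncol(mu))
  } else {
    counts <- camera$offset + mu / camera$inverse_gain
  }
  counts
}
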