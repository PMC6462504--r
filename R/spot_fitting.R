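# Spot detection and 2-D Gaussian fitting on photon images.

# separable Gaussian smoothing (matched filter for spot detection)
.gauss_smooth <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, 0, sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  sm <- apply(img, 2, pad_conv)
  t(apply(t(sm), 2, pad_conv))
}

# strict local maxima over the 8-neighborhood
.local_maxima <- function(img) {
  n <- nrow(img); m <- ncol(img)
  p <- matrix(-Inf, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- img
  best <- matrix(-Inf, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    best <- pmax(best, p[(2 + di):(n + 1 + di), (2 + dj):(m + 1 + dj)])
  }
  which(img > best, arr.ind = TRUE)
}

#' Detect diffraction-limited spot candidates
#'
#' Local maxima of the background-subtracted photon image above a
#' threshold, with a conservative overlap policy: any two candidates closer
#' than `min_separation` are *both* discarded, so near-coincident emitters
#' cannot bias the brightness statistics.
#'
#' Detection runs on a Gaussian-smoothed (matched-filter) copy of the
#' image, which suppresses pixel noise by roughly the PSF area while
#' preserving diffraction-limited peaks; the subsequent Gaussian fit uses
#' the raw image.
#'
#' @param photons photon image (matrix), e.g. from [counts_to_photons()].
#' @param detection_threshold peak height above local background in the
#'   smoothed image (photons); `NULL` uses `5 * mad(smoothed image)`
#'   (a ~5-sigma noise threshold).
#' @param min_separation minimal pairwise candidate distance (pixels).
#' @param region optional `c(row_min, row_max, col_min, col_max)` restricting
#'   detection (e.g. the bleached analysis region).
#' @param smooth_sigma matched-filter Gaussian sigma in pixels (default
#'   1.25, the typical PSF width; 0 disables smoothing).
#' @return data.frame with columns `row`, `col`, `peak` (background-
#'   subtracted smoothed peak height, photons). Zero rows is a valid
#'   result.
#' @export
detect_spots <- function(photons, detection_threshold = NULL,
                         min_separation = 4, region = NULL,
                         smooth_sigma = 1.25) {
  stopifnot(is.matrix(photons))
  sub <- if (is.null(region)) photons else
    photons[region[1]:region[2], region[3]:region[4]]
  bg <- stats::median(sub)
  img <- .gauss_smooth(photons - bg, smooth_sigma)
  if (is.null(detection_threshold)) {
    subsm <- if (is.null(region)) img else
      img[region[1]:region[2], region[3]:region[4]]
    detection_threshold <- 5 * stats::mad(subsm)
  }
  lm <- .local_maxima(img)
  # border pixels are unfittable and carry smoothing-padding artifacts
  bord <- max(2L, ceiling(3 * smooth_sigma))
  keep <- lm[, 1] > bord & lm[, 1] <= nrow(img) - bord &
    lm[, 2] > bord & lm[, 2] <= ncol(img) - bord
  lm <- lm[keep, , drop = FALSE]
  if (!is.null(region)) {
    keep <- lm[, 1] >= region[1] & lm[, 1] <= region[2] &
      lm[, 2] >= region[3] & lm[, 2] <= region[4]
    lm <- lm[keep, , drop = FALSE]
  }
  vals <- img[lm]
  ok <- vals >= detection_threshold
  lm <- lm[ok, , drop = FALSE]
  vals <- vals[ok]
  if (nrow(lm) > 1) {
    d <- as.matrix(stats::dist(lm))
    diag(d) <- Inf
    crowded <- apply(d < min_separation, 1, any)
    lm <- lm[!crowded, , drop = FALSE]
    vals <- vals[!crowded]
  }
  data.frame(row = lm[, 1], col = lm[, 2], peak = vals)
}

#' Fit a 2-D Gaussian to one spot candidate
#'
#' Levenberg-Marquardt least squares of
#' `b + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2))` on a square window
#' around the candidate; the local background `b` starts at the median of
#' the window's border pixels. The integrated single-spot brightness is
#' `B = 2 * pi * A * sigma^2` (photons). Fits are rejected — with a reason
#' code, never silently — when they fail to converge, the amplitude is not
#' positive, or sigma falls outside the configured band around the optical
#' PSF width.
#'
#' @param photons photon image.
#' @param candidate one-row data.frame (or list) with `row`, `col`.
#' @param camera a [camera_model()] (pixel size and nominal PSF sigma).
#' @param fit_window window edge in pixels (odd, default 7).
#' @param psf_band acceptance band for sigma as multiples of
#'   `camera$psf_sigma` (default `c(0.7, 1.5)`).
#' @param min_amplitude smallest acceptable fitted amplitude (photons/pixel).
#' @return One-row data.frame: `x`, `y`, `sigma` (micrometers),
#'   `brightness_B`, `background`, `fit_uncertainty` (photons), `status`
#'   (`"ok"` or a rejection code: `"edge"`, `"no_convergence"`,
#'   `"low_amplitude"`, `"sigma_out_of_band"`).
#' @export
fit_gaussian_spot <- function(photons, candidate, camera, fit_window = 7,
                              psf_band = c(0.7, 1.5), min_amplitude = 3) {
  stopifnot(is.matrix(photons), inherits(camera, "camera_model"),
            fit_window %% 2 == 1, fit_window >= 5)
  half <- (fit_window - 1) / 2
  r0 <- candidate$row; c0 <- candidate$col
  bad <- function(status) data.frame(
    x = NA_real_, y = NA_real_, sigma = NA_real_, brightness_B = NA_real_,
    background = NA_real_, fit_uncertainty = NA_real_, status = status)
  if (r0 - half < 1 || r0 + half > nrow(photons) ||
      c0 - half < 1 || c0 + half > ncol(photons)) {
    return(bad("edge"))
  }
  win <- photons[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
  border <- c(win[1, ], win[fit_window, ], win[-c(1, fit_window), 1],
              win[-c(1, fit_window), fit_window])
  bg0 <- stats::median(border)
  rel <- -half:half
  dat <- data.frame(z = as.vector(win),
                    yc = rep(rel, times = fit_window),
                    xc = rep(rel, each = fit_window))
  s0 <- camera$psf_sigma / camera$pixel_size
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((xc - x0)^2 + (yc - y0)^2) / (2 * s^2)),
      data = dat,
      start = list(b = bg0, A = max(win[half + 1, half + 1] - bg0, 1),
                   x0 = 0, y0 = 0, s = s0),
      lower = c(b = -Inf, A = -Inf, x0 = -half, y0 = -half, s = 0.2 * s0),
      upper = c(b = Inf, A = Inf, x0 = half, y0 = half, s = 5 * s0),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad("no_convergence"))
  p <- stats::coef(fit)
  if (!all(is.finite(p))) return(bad("no_convergence"))
  if (p[["A"]] < min_amplitude) return(bad("low_amplitude"))
  s_px <- p[["s"]]
  if (s_px < psf_band[1] * s0 || s_px > psf_band[2] * s0) {
    return(bad("sigma_out_of_band"))
  }
  B <- 2 * pi * p[["A"]] * s_px^2
  se_B <- tryCatch({
    V <- stats::vcov(fit)[c("A", "s"), c("A", "s")]
    g <- c(2 * pi * s_px^2, 4 * pi * p[["A"]] * s_px)
    sqrt(drop(t(g) %*% V %*% g))
  }, error = function(e) NA_real_)
  data.frame(
    x = (c0 - 1 + 0.5 + p[["x0"]]) * camera$pixel_size,
    y = (r0 - 1 + 0.5 + p[["y0"]]) * camera$pixel_size,
    sigma = s_px * camera$pixel_size,
    brightness_B = B, background = p[["b"]],
    fit_uncertainty = se_B, status = "ok")
}

#' Detect and fit all spots in a photon image
#'
#' Convenience wrapper chaining [detect_spots()] and [fit_gaussian_spot()].
#'
#' @inheritParams detect_spots
#' @inheritParams fit_gaussian_spot
#' @param frame_index stored in the output table.
#' @param keep_rejected keep rejected fits (with their status codes)?
#' @return Spot table: one row per candidate with the [fit_gaussian_spot()]
#'   columns plus `frame_index`.
#' @export
fit_spots <- function(photons, camera, detection_threshold = NULL,
                      min_separation = 4, region = NULL, fit_window = 7,
                      psf_band = c(0.7, 1.5), frame_index = 1L,
                      keep_rejected = FALSE) {
  cand <- detect_spots(photons, detection_threshold, min_separation, region,
                       smooth_sigma = camera$psf_sigma / camera$pixel_size)
  if (nrow(cand) == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      brightness_B = numeric(0), background = numeric(0),
                      fit_uncertainty = numeric(0), status = character(0))
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      fit_gaussian_spot(photons, cand[i, ], camera, fit_window, psf_band)
    }))
  }
  out$frame_index <- rep(as.integer(frame_index), nrow(out))
  if (!keep_rejected) out <- out[out$status == "ok", , drop = FALSE]
  out
}

#' Estimate the labeled-molecule surface density from a pre-bleach image
#'
#' Intensity-based estimator, usable at densities where single molecules
#' are not resolvable: total background-corrected photons divided by the
#' mean single-fluorophore brightness and the imaged area, reported per
#' um^2. Spot counting (at low density) is available as a cross-check via
#' [fit_spots()].
#'
#' @param photons pre-bleach photon image.
#' @param camera a [camera_model()].
#' @param monomer_mean_brightness mean single-fluorophore brightness
#'   (photons), from the calibration.
#' @param background_photons expected background photons per pixel,
#'   subtracted before integrating.
#' @return An object of class `density_estimate`: list with `density`
#'   (molecules per um^2), `analyzed_area` (um^2), `basis`.
#' @export
estimate_density <- function(photons, camera, monomer_mean_brightness,
                             background_photons = 0) {
  stopifnot(is.matrix(photons), inherits(camera, "camera_model"),
            monomer_mean_brightness > 0)
  area <- length(photons) * camera$pixel_size^2
  if (area <= 0) stop("analyzed area is zero")
  total <- sum(photons) - background_photons * length(photons)
  dens_raw <- total / (monomer_mean_brightness * area)
  if (dens_raw < -0.05) {
    stop("background-corrected intensity is negative; check calibration")
  }
  structure(
    list(density = max(dens_raw, 0),
         analyzed_area = area,
         basis = "integrated intensity / (monomer brightness x area)"),
    class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %.3g molecules/um^2 over %.3g um^2 (%s)\n",
              x$density, x$analyzed_area, x$basis))
  invisible(x)
}
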