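# Movie-level simulators: full TOCCSL image sequences and FRAP stacks.
# Complexes carry co-located subunits; positions are continuous (um) on a
# domain extending beyond the field of view by a margin, with periodic
# wrap-around so the surface density is conserved.

# diffuse positions on a torus [lo, hi) x [lo, hi)
.diffuse <- function(xy, D, dt, lo, hi) {
  if (dt <= 0) return(xy)
  n <- nrow(xy)
  sd_step <- sqrt(2 * D * dt)  # vectorized over molecules (0 for immobile)
  xy[, 1] <- xy[, 1] + stats::rnorm(n, 0, sd_step)
  xy[, 2] <- xy[, 2] + stats::rnorm(n, 0, sd_step)
  span <- hi - lo
  xy[, 1] <- lo + (xy[, 1] - lo) %% span
  xy[, 2] <- lo + (xy[, 2] - lo) %% span
  xy
}

.in_rect <- function(xy, rect) {
  xy[, 1] >= rect[3] & xy[, 1] < rect[4] & xy[, 2] >= rect[1] & xy[, 2] < rect[2]
}

#' Simulate a full TOCCSL image sequence
#'
#' Generates the four-phase protocol on one cell region: a pre-bleach image
#' of the full-density membrane, an 800-ms bleach pulse confined to a
#' rectangular field-stop region (executed in substeps, so complexes
#' diffusing across the aperture edge during the pulse are partially
#' bleached), a post-bleach control image, and a recovery image in which
#' unbleached complexes that diffused back into the bleached region appear
#' as resolvable diffraction-limited spots. Camera counts follow
#' `offset + photons / inverse_gain` with Poisson shot noise and Gaussian
#' read noise.
#'
#' @param truth a [ground_truth()].
#' @param timings a [protocol_timings()].
#' @param camera a [camera_model()].
#' @param bleach_region_um bleached rectangle `c(ymin, ymax, xmin, xmax)` in
#'   micrometers; default: the central 60 percent of the field of view.
#' @param margin_um width of the off-camera reservoir around the field of
#'   view (micrometers).
#' @param bleach_survival probability that a fluorophore continuously inside
#'   the bleach region survives the full pulse (0 = complete bleaching;
#'   use > 0 to emulate an incomplete bleach).
#' @param n_bleach_substeps number of diffusion/bleach substeps in the pulse.
#' @param background_photons expected background photons per pixel per frame.
#' @param spot_density_limit resolvable-spot limit (spots per um^2) for the
#'   recovery frame; exceeding it records a warning in the stack metadata.
#' @param seed integer seed (default `truth$seed`).
#' @return A [frame_stack()] with roles `pre-bleach`, `post-bleach`,
#'   `recovery`; `metadata` holds the ground truth, the complex table at the
#'   recovery frame (`complexes`), `bleach_end` (s), and any warnings.
#' @export
simulate_toccsl_movie <- function(truth, timings = protocol_timings(),
                                  camera = camera_model(),
                                  bleach_region_um = NULL,
                                  margin_um = 2,
                                  bleach_survival = 0,
                                  n_bleach_substeps = 8,
                                  background_photons = 0,
                                  spot_density_limit = 1,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(timings, "protocol_timings"),
            inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  ny <- camera$field_of_view[1]; nx <- camera$field_of_view[2]
  Ly <- ny * camera$pixel_size; Lx <- nx * camera$pixel_size
  if (is.null(bleach_region_um)) {
    bleach_region_um <- c(0.2 * Ly, 0.8 * Ly, 0.2 * Lx, 0.8 * Lx)
  }
  if (bleach_region_um[1] < 0 || bleach_region_um[2] > Ly ||
      bleach_region_um[3] < 0 || bleach_region_um[4] > Lx) {
    stop("bleach region must lie inside the field of view")
  }
  lo <- -margin_um; hi <- max(Lx, Ly) + margin_um
  area_domain <- (hi - lo)^2

  mean_size <- sum(seq_along(truth$alpha_true) * truth$alpha_true)
  n_complex <- stats::rpois(1, truth$surface_density / mean_size * area_domain)
  n_complex <- max(n_complex, 1)
  pop <- complex_population(n_complex, truth$alpha_true,
                            truth$labeling_fraction)
  xy <- cbind(stats::runif(n_complex, lo, hi), stats::runif(n_complex, lo, hi))
  mobile <- stats::runif(n_complex) < truth$mobile_fraction
  Dvec <- ifelse(mobile, truth$diffusion_coeff, 0)

  draw_emitters <- function() {
    fl <- which(pop$fluorescent)
    if (length(fl) == 0) {
      return(data.frame(x = numeric(0), y = numeric(0), photons = numeric(0)))
    }
    cid <- pop$complex_id[fl]
    data.frame(x = xy[cid, 1], y = xy[cid, 2],
               photons = rbrightness(length(fl),
                                     truth$monomer_brightness_mean,
                                     truth$monomer_brightness_cv))
  }
  render <- function() render_frame(draw_emitters(), camera,
                                    background_photons, noise = TRUE)

  # --- timeline (seconds) ---
  t_pre <- 0
  bleach_start <- timings$t_pre / 1000
  bleach_end <- bleach_start + timings$t_bleach / 1000
  t_post <- bleach_end + timings$t_post / 1000
  t_rec <- bleach_end + timings$t_recovery / 1000

  frames <- array(0, c(ny, nx, 3))
  frames[, , 1] <- render()

  # bleach pulse: diffuse and switch off fluorophores inside the region
  dt_sub <- (timings$t_bleach / 1000) / n_bleach_substeps
  p_sub <- if (bleach_survival <= 0) 1 else 1 - bleach_survival^(1 / n_bleach_substeps)
  xy <- .diffuse(xy, Dvec, bleach_start - t_pre, lo, hi)
  for (s in seq_len(n_bleach_substeps)) {
    xy <- .diffuse(xy, Dvec, dt_sub, lo, hi)
    inside <- .in_rect(xy, bleach_region_um)
    hit <- inside[pop$complex_id] & pop$fluorescent
    if (p_sub >= 1) {
      pop$fluorescent[hit] <- FALSE
    } else {
      h <- which(hit)
      pop$fluorescent[h[stats::runif(length(h)) < p_sub]] <- FALSE
    }
  }

  xy <- .diffuse(xy, Dvec, t_post - bleach_end, lo, hi)
  frames[, , 2] <- render()
  xy <- .diffuse(xy, Dvec, t_rec - t_post, lo, hi)
  frames[, , 3] <- render()

  # visible complexes inside the analysis (= bleached) region at recovery
  vis <- tapply(pop$fluorescent, pop$complex_id, any)
  inside <- .in_rect(xy, bleach_region_um)
  n_vis_in <- sum(vis & inside[as.integer(names(vis))])
  area_region <- (bleach_region_um[2] - bleach_region_um[1]) *
    (bleach_region_um[4] - bleach_region_um[3])
  warnings <- character(0)
  if (n_vis_in / area_region > spot_density_limit) {
    warnings <- sprintf(
      "recovery spot density %.2f /um^2 exceeds the %.2f /um^2 separation limit",
      n_vis_in / area_region, spot_density_limit)
  }

  complexes <- data.frame(
    complex_id = seq_len(n_complex),
    size = tapply(pop$size, pop$complex_id, function(z) z[1]),
    n_fluorescent = as.integer(tapply(pop$fluorescent, pop$complex_id, sum)),
    x = xy[, 1], y = xy[, 2], mobile = mobile)

  frame_stack(
    frames,
    timestamps = c(t_pre, t_post, t_rec),
    roles = c("pre-bleach", "post-bleach", "recovery"),
    bleach_region = um_rect_to_px(bleach_region_um, camera),
    camera = camera,
    metadata = list(truth = unclass(truth), bleach_end = bleach_end,
                    bleach_region_um = bleach_region_um,
                    complexes = complexes, warnings = warnings)
  )
}

#' Simulate a FRAP image stack
#'
#' A dense field of fluorescent molecules is imaged once, a rectangular
#' region is bleached instantaneously, and recovery frames are recorded as
#' mobile molecules from the surrounding reservoir repopulate the region.
#' Immobile molecules (fraction `1 - mobile_fraction`) bleached inside the
#' region never recover, so the recovery plateau reports the mobile
#' fraction. Rendering bins molecules into pixels (no PSF): FRAP analysis
#' integrates regions, so sub-pixel structure is irrelevant.
#'
#' @param truth a [ground_truth()] (uses `surface_density`,
#'   `diffusion_coeff`, `mobile_fraction`, `monomer_brightness_mean`).
#' @param camera a [camera_model()]; FRAP stacks use coarse pixels by
#'   default.
#' @param bleach_region_um bleached rectangle `c(ymin, ymax, xmin, xmax)`
#'   in micrometers; default: central square covering ~40 percent of the
#'   field linearly.
#' @param timestamps recovery-frame times in seconds after the bleach
#'   (strictly increasing, > 0).
#' @param reservoir_margin_um width of the unbleached off-camera reservoir.
#' @param background_photons background photons per pixel per frame.
#' @param bleach_all set every molecule dark regardless of position
#'   (control fixture).
#' @param skip_bleach record the "recovery" frames without bleaching
#'   (control fixture: curve stays at 1).
#' @param seed integer seed (default `truth$seed`).
#' @return A [frame_stack()] with one `pre-bleach` frame (at t = -1 s) and
#'   `recovery` frames at `timestamps`; `metadata$bleach_end = 0`.
#' @export
simulate_frap_stack <- function(truth,
                                camera = camera_model(pixel_size = 0.5,
                                                      field_of_view = c(32L, 32L),
                                                      psf_sigma = 0.25),
                                bleach_region_um = NULL,
                                timestamps = seq(0.5, 60, by = 0.5),
                                reservoir_margin_um = 15,
                                background_photons = 0,
                                bleach_all = FALSE,
                                skip_bleach = FALSE,
                                seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(camera, "camera_model"),
            all(timestamps > 0), all(diff(timestamps) > 0))
  if (!is.null(seed)) set.seed(seed)
  ny <- camera$field_of_view[1]; nx <- camera$field_of_view[2]
  px <- camera$pixel_size
  Ly <- ny * px; Lx <- nx * px
  if (is.null(bleach_region_um)) {
    w <- 0.2 * min(Lx, Ly)
    bleach_region_um <- c(Ly / 2 - w, Ly / 2 + w, Lx / 2 - w, Lx / 2 + w)
  }
  lo <- -reservoir_margin_um; hi <- max(Lx, Ly) + reservoir_margin_um
  area_domain <- (hi - lo)^2
  n_mol <- stats::rpois(1, truth$surface_density * area_domain)
  xy <- cbind(stats::runif(n_mol, lo, hi), stats::runif(n_mol, lo, hi))
  mobile <- stats::runif(n_mol) < truth$mobile_fraction
  Dvec <- ifelse(mobile, truth$diffusion_coeff, 0)
  fluor <- rep(TRUE, n_mol)
  b <- truth$monomer_brightness_mean

  render <- function() {
    mu <- matrix(background_photons, ny, nx)
    keep <- fluor & xy[, 1] >= 0 & xy[, 1] < Lx & xy[, 2] >= 0 & xy[, 2] < Ly
    if (any(keep)) {
      i <- floor(xy[keep, 2] / px) + 1
      j <- floor(xy[keep, 1] / px) + 1
      idx <- (j - 1) * ny + i
      acc <- tabulate(idx, nbins = ny * nx) * b
      mu <- mu + matrix(acc, ny, nx)
    }
    ph <- matrix(stats::rpois(length(mu), mu), ny, nx)
    camera$offset + ph / camera$inverse_gain +
      matrix(stats::rnorm(length(mu), 0, camera$read_noise_sd), ny, nx)
  }

  nf <- length(timestamps) + 1
  frames <- array(0, c(ny, nx, nf))
  frames[, , 1] <- render()
  if (bleach_all) {
    fluor[] <- FALSE
  } else if (!skip_bleach) {
    fluor[.in_rect(xy, bleach_region_um)] <- FALSE
  }
  t_prev <- 0
  for (k in seq_along(timestamps)) {
    xy <- .diffuse(xy, Dvec, timestamps[k] - t_prev, lo, hi)
    t_prev <- timestamps[k]
    frames[, , k + 1] <- render()
  }
  frame_stack(
    frames,
    timestamps = c(-1, timestamps),
    roles = c("pre-bleach", rep("recovery", length(timestamps))),
    bleach_region = um_rect_to_px(bleach_region_um, camera),
    camera = camera,
    metadata = list(truth = unclass(truth), bleach_end = 0,
                    bleach_region_um = bleach_region_um)
  )
}
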