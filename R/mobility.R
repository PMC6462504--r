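# FRAP mobile-fraction and MSD diffusion estimation.

#' Normalize a FRAP stack to a recovery curve
#'
#' Integrates the photon counts in the central part of the bleached region
#' (the bleach rectangle eroded by `central_margin` per side) for every
#' recovery frame and normalizes to the same integral in the pre-bleach
#' frame(s), yielding the dimensionless I/I0 curve with time zero at the
#' end of the bleach pulse.
#'
#' @param stack a [frame_stack()] with at least one `pre-bleach` frame and
#'   one or more `recovery` frames; `metadata$bleach_end` (s) marks time
#'   zero (default: the last pre-bleach timestamp).
#' @param bleach_roi bleach rectangle in pixels `c(rmin, rmax, cmin, cmax)`
#'   (default `stack$bleach_region`).
#' @param central_margin fraction of the ROI eroded per side (default 0.25,
#'   i.e. the central 50 percent per axis is evaluated).
#' @return data.frame with columns `t` (s since end of bleach) and
#'   `intensity` (I/I0).
#' @export
normalize_frap <- function(stack, bleach_roi = NULL, central_margin = 0.25) {
  stopifnot(inherits(stack, "frame_stack"),
            central_margin >= 0, central_margin < 0.5)
  if (is.null(bleach_roi)) bleach_roi <- stack$bleach_region
  dr <- floor((bleach_roi[2] - bleach_roi[1] + 1) * central_margin)
  dc <- floor((bleach_roi[4] - bleach_roi[3] + 1) * central_margin)
  roi <- c(bleach_roi[1] + dr, bleach_roi[2] - dr,
           bleach_roi[3] + dc, bleach_roi[4] - dc)
  roi_sum <- function(ph) sum(ph[roi[1]:roi[2], roi[3]:roi[4]])
  pre <- stack_photons(stack, "pre-bleach")
  if (length(pre) == 0) stop("stack has no pre-bleach frame")
  I0 <- mean(vapply(pre, roi_sum, numeric(1)))
  if (I0 <= 0) stop("pre-bleach ROI intensity I0 <= 0")
  rec_idx <- which(stack$roles == "recovery")
  if (length(rec_idx) == 0) stop("stack has no recovery frames")
  I <- vapply(rec_idx, function(i) {
    roi_sum(counts_to_photons(stack$frames[, , i], stack$camera))
  }, numeric(1))
  t0 <- stack$metadata$bleach_end
  if (is.null(t0)) t0 <- max(stack$timestamps[stack$roles == "pre-bleach"])
  data.frame(t = stack$timestamps[rec_idx] - t0, intensity = I / I0)
}

#' Fit the FRAP recovery model
#'
#' Bounded least squares of `I/I0 = m * (1 - exp(-t / tau))` with mobile
#' fraction `m` in `[0, 1]` and `tau > 0` (Levenberg-Marquardt). A curve
#' with no measurable recovery is returned as `m = 0` with
#' `tau_unidentifiable` flagged; a plateau not reached within the observed
#' window (`max(t) < 2 tau`) is flagged `plateau_not_reached`.
#'
#' @param curve data.frame with columns `t` (s) and `intensity`, e.g. from
#'   [normalize_frap()] or [simulate_frap_curve()].
#' @param weights optional least-squares weights.
#' @return An object of class `frap_fit`: `mobile_fraction`, `tau`,
#'   `mobile_fraction_se`, `tau_se`, `n_timepoints`, `flags` (character
#'   vector, possibly empty).
#' @export
fit_frap <- function(curve, weights = NULL) {
  stopifnot(is.data.frame(curve), all(c("t", "intensity") %in% names(curve)))
  curve <- curve[is.finite(curve$intensity) & curve$t >= 0, ]
  if (nrow(curve) < 5) stop("need at least 5 timepoints to fit the recovery")
  if (is.null(weights)) weights <- rep(1, nrow(curve))
  flags <- character(0)
  plateau0 <- mean(utils::tail(curve$intensity, max(3, nrow(curve) %/% 5)))
  if (plateau0 < 0.02) {
    return(structure(
      list(mobile_fraction = 0, tau = NA_real_,
           mobile_fraction_se = NA_real_, tau_se = NA_real_,
           n_timepoints = nrow(curve), flags = "tau_unidentifiable"),
      class = "frap_fit"))
  }
  i63 <- which(curve$intensity >= 0.63 * plateau0)
  tau0 <- if (length(i63)) max(curve$t[i63[1]], 1e-3) else max(curve$t) / 2
  fit <- minpack.lm::nlsLM(
    intensity ~ m * (1 - exp(-t / tau)), data = curve,
    start = list(m = min(max(plateau0, 1e-3), 1), tau = tau0),
    lower = c(m = 0, tau = 1e-6), upper = c(m = 1, tau = Inf),
    weights = weights,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(m = NA_real_, tau = NA_real_))
  if (max(curve$t) < 2 * p[["tau"]]) flags <- c(flags, "plateau_not_reached")
  structure(
    list(mobile_fraction = p[["m"]], tau = p[["tau"]],
         mobile_fraction_se = unname(se["m"]), tau_se = unname(se["tau"]),
         n_timepoints = nrow(curve), flags = flags),
    class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile fraction %.3f +/- %.3f | tau %.3g +/- %.3g s | %d points%s\n",
              x$mobile_fraction, x$mobile_fraction_se, x$tau, x$tau_se,
              x$n_timepoints,
              if (length(x$flags)) paste0(" | flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Mean square displacement versus time lag
#'
#' Time-averaged MSD with overlapping pairs within each track, then
#' averaged across tracks weighted by the number of contributing pairs.
#' Standard errors are the weighted between-track dispersion.
#'
#' @param trajectories data.frame with columns `track_id`, `t`, `x`, `y`
#'   (e.g. from [simulate_trajectories()]); the time base must be uniform.
#' @param max_lag largest lag in steps; truncated (with a warning) to the
#'   longest track.
#' @return data.frame with columns `lag` (s), `msd` (um^2), `se`,
#'   `n_pairs`.
#' @export
compute_msd <- function(trajectories, max_lag = 5) {
  stopifnot(is.data.frame(trajectories),
            all(c("track_id", "t", "x", "y") %in% names(trajectories)))
  tracks <- split(trajectories, trajectories$track_id)
  lens <- vapply(tracks, nrow, integer(1))
  if (min(lens) < 2) stop("every trajectory needs at least 2 points")
  dts <- unlist(lapply(tracks, function(tr) diff(tr$t)))
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-9 * dt) stop("time base must be uniform")
  if (max_lag >= max(lens)) {
    warning("max_lag exceeds the longest trajectory; truncating")
    max_lag <- max(lens) - 1
  }
  out <- lapply(seq_len(max_lag), function(k) {
    per <- vapply(tracks, function(tr) {
      n <- nrow(tr)
      if (n <= k) return(c(NA_real_, 0))
      dx <- tr$x[(k + 1):n] - tr$x[1:(n - k)]
      dy <- tr$y[(k + 1):n] - tr$y[1:(n - k)]
      c(mean(dx^2 + dy^2), n - k)
    }, numeric(2))
    m <- per[1, ]; w <- per[2, ]
    ok <- is.finite(m) & w > 0
    m <- m[ok]; w <- w[ok]
    msd <- sum(w * m) / sum(w)
    se <- if (length(m) > 1) {
      sqrt(sum(w * (m - msd)^2) / sum(w) / (length(m) - 1))
    } else NA_real_
    data.frame(lag = k * dt, msd = msd, se = se, n_pairs = sum(w))
  })
  do.call(rbind, out)
}

#' Diffusion coefficient from an MSD curve
#'
#' Default estimator: the exact line through the first two MSD points,
#' `MSD = 4 D t_lag + offset`, so `D = slope / 4` and the intercept is the
#' (localization-error) offset, which is reported but never subtracted.
#' `mode = "wls"` fits all lags by weighted least squares instead.
#'
#' @param msd data.frame from [compute_msd()] (columns `lag`, `msd`,
#'   optionally `se`).
#' @param mode `"two-point"` (default) or `"wls"`.
#' @return An object of class `diffusion_fit`: `D` (um^2/s, clipped at 0
#'   with a flag if the slope is negative), `offset` (um^2), `se_D`,
#'   `lags_used`, `flags`.
#' @export
fit_diffusion <- function(msd, mode = c("two-point", "wls")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(msd), all(c("lag", "msd") %in% names(msd)))
  if (nrow(msd) < 2) stop("need at least 2 lags")
  flags <- character(0)
  if (mode == "two-point") {
    slope <- (msd$msd[2] - msd$msd[1]) / (msd$lag[2] - msd$lag[1])
    offset <- msd$msd[1] - slope * msd$lag[1]
    se_D <- if (!is.null(msd$se) && all(is.finite(msd$se[1:2]))) {
      sqrt(msd$se[1]^2 + msd$se[2]^2) / (msd$lag[2] - msd$lag[1]) / 4
    } else NA_real_
    lags_used <- 2L
  } else {
    w <- if (!is.null(msd$se) && all(is.finite(msd$se))) 1 / msd$se^2 else NULL
    fm <- stats::lm(msd ~ lag, data = msd, weights = w)
    slope <- stats::coef(fm)[["lag"]]
    offset <- stats::coef(fm)[["(Intercept)"]]
    se_D <- summary(fm)$coefficients["lag", "Std. Error"] / 4
    lags_used <- nrow(msd)
  }
  D <- slope / 4
  if (D < 0) {
    D <- 0
    flags <- c(flags, "negative_slope_clipped")
  }
  structure(
    list(D = D, offset = offset, se_D = se_D, lags_used = lags_used,
         flags = flags),
    class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g um^2/s | offset %.3g um^2 | %d lags%s\n",
              x$D, x$se_D, x$offset, x$lags_used,
              if (length(x$flags)) paste0(" | flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}
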