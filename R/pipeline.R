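# End-to-end TOCCSL orchestration: frames -> spots -> mixture -> report,
# repeat-TOCCSL stability analysis and condition-group comparisons.

#' Analysis configuration for the TOCCSL pipeline
#'
#' @param detection_threshold spot detection threshold (photons); `NULL`
#'   for the automatic 5-sigma noise threshold.
#' @param min_separation minimal spot separation (pixels).
#' @param fit_window Gaussian fit window (pixels, odd).
#' @param psf_band accepted sigma band (multiples of the nominal PSF sigma).
#' @param completeness_max_density maximal residual spot density in the
#'   post-bleach control image (spots per um^2) for a run to be valid.
#' @param analysis_margin_um erosion of the analysis region border
#'   (micrometers) to avoid spots contaminated by the unbleached surround.
#' @param n_max largest oligomer order fitted.
#' @param min_spots_for_fit smallest pooled sample for a mixture fit.
#' @param background_photons expected background photons per pixel.
#' @return A list of class `toccsl_config`.
#' @export
toccsl_config <- function(detection_threshold = NULL, min_separation = 4,
                          fit_window = 7, psf_band = c(0.7, 1.5),
                          completeness_max_density = 0.01,
                          analysis_margin_um = 0.5, n_max = 5,
                          min_spots_for_fit = 200, background_photons = 0) {
  structure(as.list(environment()), class = "toccsl_config")
}

# erode a pixel rectangle by a margin given in micrometers
.erode_px <- function(rect, margin_um, pixel_size) {
  m <- ceiling(margin_um / pixel_size)
  out <- c(rect[1] + m, rect[2] - m, rect[3] + m, rect[4] - m)
  if (out[1] > out[2] || out[3] > out[4]) rect else out
}

#' Run the TOCCSL analysis on one image sequence
#'
#' The full per-run protocol: surface density from the pre-bleach image,
#' bleaching-completeness check on the post-bleach control image (a run
#' with residual spots above the configured density is invalid and yields
#' no mixture fit), then spot detection and Gaussian fitting on the
#' recovery frame(s) restricted to the (eroded) bleached analysis region.
#' If a calibrated monomer density `rho1` is supplied and enough spots were
#' accepted, the oligomer mixture is fitted.
#'
#' @param stack a [frame_stack()] with roles `pre-bleach`, `post-bleach`
#'   and `recovery` (e.g. from [simulate_toccsl_movie()]).
#' @param rho1 optional monomer `brightness_pdf` for the mixture fit.
#' @param config a [toccsl_config()].
#' @param run_index,elapsed,condition,cell_id metadata carried into the run.
#' @return An object of class `toccsl_run`: `density`
#'   (a `density_estimate`), `post_residual_density` (spots per um^2),
#'   `valid`, `spots` (accepted spot table), `brightness` (accepted B
#'   values, photons), `mixture` (`mixture_result` or NULL), plus the
#'   metadata fields.
#' @export
run_toccsl_analysis <- function(stack, rho1 = NULL, config = toccsl_config(),
                                run_index = 1L, elapsed = 0,
                                condition = "untreated", cell_id = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  camera <- stack$camera
  need <- c("pre-bleach", "post-bleach", "recovery")
  if (!all(need %in% stack$roles)) {
    stop("stack must contain pre-bleach, post-bleach and recovery frames")
  }
  px_area <- camera$pixel_size^2
  region <- stack$bleach_region
  region_area <- (region[2] - region[1] + 1) * (region[4] - region[3] + 1) * px_area

  monomer_mean <- if (!is.null(rho1)) pdf_mean(rho1) else
    stack$metadata$truth$monomer_brightness_mean
  if (is.null(monomer_mean)) {
    stop("monomer mean brightness unknown: supply rho1 or stack metadata")
  }
  pre_idx <- which(stack$roles == "pre-bleach")[1]
  pre <- counts_to_photons(stack$frames[, , pre_idx], camera, clip = FALSE)
  density <- estimate_density(pre, camera, monomer_mean,
                              config$background_photons)

  # completeness check on the (eroded) bleached region: residual spots mean
  # the bleach pulse failed and the stoichiometry readout is compromised
  inner <- .erode_px(region, config$analysis_margin_um, camera$pixel_size)
  inner_area <- (inner[2] - inner[1] + 1) * (inner[4] - inner[3] + 1) * px_area
  post <- stack_photons(stack, "post-bleach")[[1]]
  post_cand <- detect_spots(post, config$detection_threshold,
                            config$min_separation, region = inner,
                            smooth_sigma = camera$psf_sigma / camera$pixel_size)
  post_res <- nrow(post_cand) / inner_area
  valid <- post_res <= config$completeness_max_density

  spots <- NULL
  brightness <- numeric(0)
  mixture <- NULL
  if (valid) {
    analysis <- .erode_px(region, config$analysis_margin_um, camera$pixel_size)
    rec_idx <- which(stack$roles == "recovery")
    spots <- do.call(rbind, lapply(rec_idx, function(i) {
      ph <- counts_to_photons(stack$frames[, , i], camera, clip = FALSE)
      fit_spots(ph, camera, config$detection_threshold,
                config$min_separation, region = analysis,
                fit_window = config$fit_window, psf_band = config$psf_band,
                frame_index = i)
    }))
    brightness <- spots$brightness_B
    if (!is.null(rho1) && length(brightness) >= config$min_spots_for_fit) {
      mixture <- fit_mixture(brightness, rho1, config$n_max)
    }
  }
  structure(
    list(density = density, post_residual_density = post_res, valid = valid,
         spots = spots, brightness = brightness, mixture = mixture,
         run_index = as.integer(run_index), elapsed = elapsed,
         condition = condition, cell_id = cell_id),
    class = "toccsl_run")
}

#' Assemble a TOCCSL run from already-extracted quantities
#'
#' Constructor used by the population-level simulators and by analyses that
#' pool spot tables produced elsewhere.
#'
#' @param brightness accepted single-spot brightnesses (photons).
#' @param density surface density (molecules per um^2) or a
#'   `density_estimate`.
#' @param run_index,elapsed,condition,cell_id run metadata.
#' @param valid completeness status.
#' @return A `toccsl_run`.
#' @export
toccsl_run <- function(brightness, density = NA_real_, run_index = 1L,
                       elapsed = 0, condition = "untreated", cell_id = 1L,
                       valid = TRUE) {
  if (!inherits(density, "density_estimate")) {
    density <- structure(list(density = density, analyzed_area = NA_real_,
                              basis = "supplied"),
                         class = "density_estimate")
  }
  structure(
    list(density = density, post_residual_density = NA_real_, valid = valid,
         spots = NULL, brightness = as.numeric(brightness), mixture = NULL,
         run_index = as.integer(run_index), elapsed = elapsed,
         condition = condition, cell_id = cell_id),
    class = "toccsl_run")
}

#' @export
print.toccsl_run <- function(x, ...) {
  cat(sprintf(
    "<toccsl_run> run %d, cell %s, %s | density %.3g /um^2 | %d spots | %s\n",
    x$run_index, as.character(x$cell_id), x$condition, x$density$density,
    length(x$brightness), if (x$valid) "valid" else "INVALID (incomplete bleach)"))
  invisible(x)
}

#' Pool spot brightnesses across runs
#'
#' @param runs list of `toccsl_run`s.
#' @param only_valid drop invalid runs (default TRUE).
#' @return Numeric vector of pooled brightness values.
#' @export
pool_brightness <- function(runs, only_valid = TRUE) {
  unlist(lapply(runs, function(r) {
    if (only_valid && !r$valid) numeric(0) else r$brightness
  }), use.names = FALSE)
}

#' Compare oligomer distributions between density groups
#'
#' Splits runs into low- and high-density groups at `density_cut`, fits the
#' mixture (with bootstrap errors) on the pooled spots of each group and
#' reports the dimer-fraction difference with its combined standard error.
#' The same computation serves any group comparison (biochemical conditions
#' are treated as group keys via `group_by = "condition"`).
#'
#' @param runs list of `toccsl_run`s.
#' @param rho1 monomer `brightness_pdf`.
#' @param density_cut density (molecules per um^2) separating the groups.
#' @param group_by `"density"` (default) or `"condition"`.
#' @param conditions for `group_by = "condition"`: the two labels compared.
#' @param n_max,n_reps,seed fitting/bootstrap parameters.
#' @return An object of class `group_comparison`: `fit_low`, `fit_high`
#'   (mixture results with bootstrap SEs), `delta_alpha2`
#'   (high minus low), `delta_alpha2_se` (combined), `group_sizes`.
#' @export
compare_density_groups <- function(runs, rho1, density_cut = 15,
                                   group_by = c("density", "condition"),
                                   conditions = NULL, n_max = 5,
                                   n_reps = 100, seed = NULL) {
  group_by <- match.arg(group_by)
  runs <- Filter(function(r) r$valid, runs)
  if (group_by == "density") {
    dens <- vapply(runs, function(r) r$density$density, numeric(1))
    lo <- runs[dens < density_cut]
    hi <- runs[dens >= density_cut]
  } else {
    stopifnot(length(conditions) == 2)
    cond <- vapply(runs, function(r) r$condition, character(1))
    lo <- runs[cond == conditions[1]]
    hi <- runs[cond == conditions[2]]
  }
  if (length(lo) == 0 || length(hi) == 0) {
    stop("both comparison groups must be non-empty")
  }
  components <- nmer_pdfs(rho1, n_max)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, 2)
  f_lo <- fit_mixture_boot(pool_brightness(lo), components = components,
                           n_reps = n_reps, seed = seeds[1])
  f_hi <- fit_mixture_boot(pool_brightness(hi), components = components,
                           n_reps = n_reps, seed = seeds[2])
  d2 <- f_hi$alpha[2] - f_lo$alpha[2]
  se2 <- sqrt(f_hi$alpha_se[2]^2 + f_lo$alpha_se[2]^2)
  structure(
    list(fit_low = f_lo, fit_high = f_hi, delta_alpha2 = d2,
         delta_alpha2_se = se2,
         group_sizes = c(low = length(lo), high = length(hi))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> alpha2 low %.3f +/- %.3f (n=%d runs) vs high %.3f +/- %.3f (n=%d runs)\n  delta alpha2 = %.3f +/- %.3f (|delta| = %.2f combined SE)\n",
    x$fit_low$alpha[2], x$fit_low$alpha_se[2], x$group_sizes[1],
    x$fit_high$alpha[2], x$fit_high$alpha_se[2], x$group_sizes[2],
    x$delta_alpha2, x$delta_alpha2_se,
    abs(x$delta_alpha2) / x$delta_alpha2_se))
  invisible(x)
}

#' Apparent oligomer composition under stable versus exchanging subunits
#'
#' Predicts the spot-level composition seen in repeat-TOCCSL runs given the
#' complex-level composition and the unbleached-fluorophore fraction f per
#' run. Stable complexes are bleached all-or-none, so the apparent
#' composition never changes. Under fast exchange, fluorophore labels are
#' redistributed binomially: a complex of size M carries K visible
#' fluorophores with probability `choose(M, K) f^K (1-f)^(M-K)`, and
#' visible spots (K >= 1) are renormalized; for a monomer/dimer population
#' the apparent dimer fraction is
#' `d f^2 / (m f + d (2 f (1 - f) + f^2))` with `m = 1 - d`.
#'
#' @param alpha_complex complex-level size fractions (sum 1).
#' @param f unbleached-fluorophore fraction per run, each in `(0, 1]`.
#' @param regime `"stable"` or `"fast"`.
#' @return Matrix `length(f) x length(alpha_complex)`: apparent spot-level
#'   fractions per run.
#' @export
exchange_model_predict <- function(alpha_complex, f,
                                   regime = c("stable", "fast")) {
  regime <- match.arg(regime)
  if (any(alpha_complex < 0) || abs(sum(alpha_complex) - 1) > 1e-9) {
    stop("alpha_complex must be non-negative and sum to 1")
  }
  if (any(f <= 0) || any(f > 1)) {
    stop("unbleached fractions f must lie in (0, 1]")
  }
  nmax <- length(alpha_complex)
  if (regime == "stable") {
    return(matrix(alpha_complex, nrow = length(f), ncol = nmax, byrow = TRUE))
  }
  t(vapply(f, function(fk) {
    num <- vapply(seq_len(nmax), function(K) {
      sum(vapply(K:nmax, function(M) {
        alpha_complex[M] * stats::dbinom(K, M, fk)
      }, numeric(1)))
    }, numeric(1))
    num / sum(num)
  }, numeric(nmax)))
}

#' Simulate a repetitive TOCCSL experiment
#'
#' Population-level simulation of the repeat protocol on `n_cells` cells:
#' per run, mobile complexes currently inside the bleached region lose all
#' fluorophores, a recovery sample of visible complexes (>= 1 active
#' fluorophore) is recorded from the analysis region, and subunits exchange
#' at `truth$exchange_rate` during the interval to the next run. Spatial
#' transport is treated as complete mixing between runs (the 5-min interval
#' far exceeds the time to diffuse across the bleached region), so each run
#' bleaches an independent random fraction `bleach_area / cell_area` of the
#' remaining fluorophores. Immobile complexes never enter the recovery
#' sample (the protocol is blind to the immobile fraction), so the
#' simulated population is the mobile pool only.
#'
#' @param truth a [ground_truth()].
#' @param timings a [protocol_timings()] (`n_runs`, `run_interval`).
#' @param n_cells number of cells pooled per run index.
#' @param cell_area_um2 membrane area per cell.
#' @param bleach_area_um2 bleached/analysis region area.
#' @param recovery_fill fraction of the analysis region repopulated at the
#'   recovery image.
#' @param seed integer seed (default `truth$seed`).
#' @return List with `runs` (list of [toccsl_run()]s, one per cell and run
#'   index), `f_global` (unbleached fluorophore fraction after each run's
#'   bleach), `f_visible` (unbleached fraction among complexes that
#'   survived that run's bleach — the quantity the binomial exchange model
#'   takes), `n_visible` (pooled visible spots per run), `truth`.
#' @export
simulate_repeat_toccsl <- function(truth, timings = protocol_timings(),
                                   n_cells = 10, cell_area_um2 = 600,
                                   bleach_area_um2 = 100,
                                   recovery_fill = 0.6,
                                   seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(timings, "protocol_timings"),
            bleach_area_um2 < cell_area_um2)
  if (!is.null(seed)) set.seed(seed)
  p_b <- bleach_area_um2 / cell_area_um2
  mean_size <- sum(seq_along(truth$alpha_true) * truth$alpha_true)
  runs <- list()
  sub_tot <- 0L; sub_fl <- numeric(timings$n_runs)
  surv_fl <- numeric(timings$n_runs); surv_tot <- numeric(timings$n_runs)
  n_vis_tot <- integer(timings$n_runs)
  for (cell in seq_len(n_cells)) {
    n_complex <- stats::rpois(1, truth$surface_density * truth$mobile_fraction /
                                mean_size * cell_area_um2)
    pop <- complex_population(max(n_complex, 1), truth$alpha_true,
                              truth$labeling_fraction)
    for (k in seq_len(timings$n_runs)) {
      # bleach pulse: complexes currently inside the region go fully dark
      ids <- unique(pop$complex_id)
      hit_ids <- ids[stats::runif(length(ids)) < p_b]
      hit <- pop$complex_id %in% hit_ids
      pop$fluorescent[hit] <- FALSE
      sub_fl[k] <- sub_fl[k] + sum(pop$fluorescent)
      surv_fl[k] <- surv_fl[k] + sum(pop$fluorescent[!hit])
      surv_tot[k] <- surv_tot[k] + sum(!hit)
      # recovery image: visible complexes sampled into the analysis region
      nfl <- tapply(pop$fluorescent, pop$complex_id, sum)
      eligible <- as.integer(names(nfl))[nfl >= 1]
      lambda <- length(eligible) * p_b * recovery_fill
      n_vis <- min(stats::rpois(1, lambda), length(eligible))
      bright <- numeric(0)
      if (n_vis > 0) {
        chosen <- sample(eligible, n_vis)
        kfl <- as.integer(nfl[as.character(chosen)])
        draws <- rbrightness(sum(kfl), truth$monomer_brightness_mean,
                             truth$monomer_brightness_cv)
        bright <- as.numeric(tapply(draws, rep.int(seq_len(n_vis), kfl), sum))
      }
      n_vis_tot[k] <- n_vis_tot[k] + n_vis
      runs[[length(runs) + 1]] <- toccsl_run(
        bright, density = truth$surface_density, run_index = k,
        elapsed = (k - 1) * timings$run_interval, cell_id = cell)
      # subunit exchange during the interval to the next run
      if (k < timings$n_runs && truth$exchange_rate > 0) {
        pop <- apply_subunit_exchange(pop, truth$exchange_rate,
                                      timings$run_interval)
      }
    }
    sub_tot <- sub_tot + nrow(pop)
  }
  list(runs = runs,
       f_global = sub_fl / sub_tot,
       f_visible = surv_fl / pmax(surv_tot, 1e-12),
       n_visible = n_vis_tot,
       truth = truth)
}

# mean subunits per complex
mean_size_of <- function(truth) {
  sum(seq_along(truth$alpha_true) * truth$alpha_true)
}

#' Repeat-TOCCSL stability analysis
#'
#' Pools spots per run index across cells, fits the oligomer mixture with
#' bootstrap errors per index, and tests the dimer fraction for a trend: a
#' stable population keeps alpha_2 constant while the number of visible
#' spots is depleted run over run, whereas subunit exchange shifts the
#' apparent composition toward monomers. The verdict combines the weighted
#' least-squares slope of alpha_2 versus run index (|slope| < 1 SE ->
#' stable, > 2 SE -> exchanging, else inconclusive) with a comparison of
#' the constant-composition model against a two-parameter fast-exchange
#' model (geometric unbleached-fraction schedule `f_k = (1-p)^(k-1)` fed
#' through the binomial mixing prediction); a stable verdict requires the
#' constant model to be preferred.
#'
#' @param runs list of `toccsl_run`s (all cells, all run indices).
#' @param rho1 monomer `brightness_pdf`.
#' @param n_max largest oligomer order fitted.
#' @param n_reps bootstrap replicates per run index.
#' @param min_spots smallest pooled sample per run index; smaller indices
#'   are flagged and excluded from the trend.
#' @param seed integer seed.
#' @return An object of class `stability_report`: `per_run` (data.frame
#'   with run_index, n_spots, alpha1, alpha2, alpha2_se, used), `alpha`
#'   (matrix of all fractions per index), `slope`, `slope_se`, `verdict`,
#'   `depletion` (visible spots per index), `exchange_fit` (list with the
#'   fitted p, q2 and weighted SSEs of both models).
#' @export
analyze_repeat_toccsl <- function(runs, rho1, n_max = 5, n_reps = 60,
                                  min_spots = 100, seed = NULL) {
  stopifnot(length(runs) >= 1)
  idx <- vapply(runs, function(r) r$run_index, integer(1))
  kk <- sort(unique(idx))
  components <- nmer_pdfs(rho1, n_max)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, length(kk))
  per <- list(); alpha_mat <- matrix(NA_real_, length(kk), n_max)
  depletion <- integer(length(kk))
  for (i in seq_along(kk)) {
    b <- pool_brightness(runs[idx == kk[i]])
    depletion[i] <- length(b)
    if (length(b) >= min_spots) {
      fit <- fit_mixture_boot(b, components = components, n_reps = n_reps,
                              seed = seeds[i])
      alpha_mat[i, ] <- fit$alpha
      per[[i]] <- data.frame(run_index = kk[i], n_spots = length(b),
                             alpha1 = fit$alpha[1], alpha2 = fit$alpha[2],
                             alpha2_se = fit$alpha_se[2], used = TRUE)
    } else {
      per[[i]] <- data.frame(run_index = kk[i], n_spots = length(b),
                             alpha1 = NA_real_, alpha2 = NA_real_,
                             alpha2_se = NA_real_, used = FALSE)
    }
  }
  per <- do.call(rbind, per)
  use <- per$used & is.finite(per$alpha2_se) & per$alpha2_se > 0
  if (sum(use) < 2) {
    return(structure(
      list(per_run = per, alpha = alpha_mat, slope = NA_real_,
           slope_se = NA_real_, verdict = "inconclusive",
           depletion = depletion, exchange_fit = NULL),
      class = "stability_report"))
  }
  x <- per$run_index[use]; y <- per$alpha2[use]; w <- 1 / per$alpha2_se[use]^2
  xb <- sum(w * x) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * y) / sxx
  slope_se <- sqrt(1 / sxx)  # propagates the per-run bootstrap SEs
  z <- abs(slope) / slope_se
  verdict <- if (z < 1) "stable" else if (z > 2) "exchanging" else "inconclusive"

  # constant model vs fast-exchange model (geometric bleach schedule)
  const <- sum(w * y) / sum(w)
  sse_const <- sum(w * (y - const)^2)
  obj <- function(par) {
    p <- stats::plogis(par[1]); q2 <- stats::plogis(par[2])
    f <- pmax((1 - p)^(x - 1), 1e-6)
    pred <- exchange_model_predict(c(1 - q2, q2), f, "fast")[, 2]
    sum(w * (y - pred)^2)
  }
  ex <- stats::optim(c(stats::qlogis(0.15), stats::qlogis(max(min(y[1], 0.95), 0.05))),
                     obj, method = "Nelder-Mead")
  exchange_fit <- list(p = stats::plogis(ex$par[1]),
                       q2 = stats::plogis(ex$par[2]),
                       sse_exchange = ex$value, sse_const = sse_const)
  prefer_exchange <- (ex$value + 2) < sse_const  # 1 extra parameter penalty
  if (verdict == "stable" && prefer_exchange) verdict <- "inconclusive"
  structure(
    list(per_run = per, alpha = alpha_mat, slope = slope,
         slope_se = slope_se, verdict = verdict, depletion = depletion,
         exchange_fit = exchange_fit),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> verdict: %s | alpha2 slope %.4g +/- %.4g per run\n",
              x$verdict, x$slope, x$slope_se))
  cat("  visible spots per run:", paste(x$depletion, collapse = ", "), "\n")
  invisible(x)
}
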