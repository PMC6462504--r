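#' Ground-truth parameters for synthetic experiments
#'
#' Bundles everything the generator needs to emulate a TOCCSL / FRAP /
#' tracking experiment with a known answer: the surface density of labeled
#' molecules, the true oligomer fractions, mobility, subunit-exchange rate
#' and the single-fluorophore brightness model. The defaults are the
#' plasma-membrane regime used throughout: monomer/dimer/trimer fractions
#' (0.55, 0.35, 0.10), D = 0.118 um^2/s, mobile fraction 0.78, stable
#' complexes (exchange rate 0), lognormal single-fluorophore brightness with
#' mean 100 photons and CV 0.35.
#'
#' @param surface_density labeled molecules (subunits) per um^2 (> 0).
#' @param alpha_true fractions of complexes that are N-mers, N = 1..N_max;
#'   non-negative, summing to 1 within 1e-12.
#' @param diffusion_coeff lateral diffusion coefficient D (um^2/s, >= 0).
#' @param mobile_fraction fraction of mobile molecules in `[0, 1]`;
#'   immobile molecules have D = 0 and never enter a bleached region.
#' @param exchange_rate per-subunit exchange rate between complexes (1/s);
#'   0 means stable complexes.
#' @param monomer_brightness_mean mean single-fluorophore brightness
#'   (photons per frame).
#' @param monomer_brightness_cv coefficient of variation of the
#'   single-fluorophore brightness (lognormal model); 0 gives a
#'   deterministic brightness.
#' @param labeling_fraction probability that a subunit carries an active
#'   fluorophore (default 1: no correction for dark fluorophores).
#' @param seed integer seed stored with the truth (used as default by the
#'   simulators).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(surface_density = 20,
                         alpha_true = c(0.55, 0.35, 0.10),
                         diffusion_coeff = 0.118,
                         mobile_fraction = 0.78,
                         exchange_rate = 0,
                         monomer_brightness_mean = 100,
                         monomer_brightness_cv = 0.35,
                         labeling_fraction = 1,
                         seed = NULL) {
  if (any(alpha_true < 0) || abs(sum(alpha_true) - 1) > 1e-12) {
    stop("alpha_true must be non-negative and sum to 1 (within 1e-12)")
  }
  stopifnot(surface_density > 0, diffusion_coeff >= 0,
            mobile_fraction >= 0, mobile_fraction <= 1,
            exchange_rate >= 0, monomer_brightness_mean > 0,
            monomer_brightness_cv >= 0,
            labeling_fraction > 0, labeling_fraction <= 1)
  structure(
    list(surface_density = surface_density, alpha_true = alpha_true,
         diffusion_coeff = diffusion_coeff, mobile_fraction = mobile_fraction,
         exchange_rate = exchange_rate,
         monomer_brightness_mean = monomer_brightness_mean,
         monomer_brightness_cv = monomer_brightness_cv,
         labeling_fraction = labeling_fraction, seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> density %g /um^2 | alpha = (%s) | D %g um^2/s | mobile %g | exchange %g /s\n",
    x$surface_density, paste(signif(x$alpha_true, 3), collapse = ", "),
    x$diffusion_coeff, x$mobile_fraction, x$exchange_rate))
  invisible(x)
}

#' TOCCSL protocol timings
#'
#' Defaults follow the measured protocol: 50 ms pre-bleach delay, 800 ms
#' bleach pulse, post-bleach control image 40 ms after the pulse, recovery
#' image after 15,000 ms (adjustable 15-20 s), and for the repetitive
#' protocol one run every 5 min, 10 runs.
#'
#' @param t_pre,t_bleach,t_post,t_recovery durations in milliseconds (> 0).
#' @param run_interval interval between repeat-TOCCSL runs in seconds.
#' @param n_runs number of repeat runs.
#' @param excitation_time stroboscopic illumination time per image (ms).
#' @return An object of class `protocol_timings`.
#' @export
protocol_timings <- function(t_pre = 50, t_bleach = 800, t_post = 40,
                             t_recovery = 15000, run_interval = 300,
                             n_runs = 10, excitation_time = 5) {
  stopifnot(t_pre > 0, t_bleach > 0, t_post > 0, t_recovery > 0,
            run_interval > 0, n_runs >= 1, excitation_time > 0)
  structure(
    list(t_pre = t_pre, t_bleach = t_bleach, t_post = t_post,
         t_recovery = t_recovery, run_interval = run_interval,
         n_runs = as.integer(n_runs), excitation_time = excitation_time),
    class = "protocol_timings"
  )
}

# lognormal single-fluorophore brightness with given mean and CV
rbrightness <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw single-spot brightness samples with known stoichiometry
#'
#' Generative counterpart of the observed spot-brightness distribution: for
#' each spot an oligomer order N is drawn from `alpha_true` and the spot
#' brightness is the sum of N independent single-fluorophore draws.
#'
#' @param truth a [ground_truth()].
#' @param n_spots number of spots (>= 1).
#' @param seed integer seed (default: `truth$seed`).
#' @return data.frame with columns `brightness` (photons) and `n_true`
#'   (the generating oligomer order, for recovery tests).
#' @export
simulate_brightness_samples <- function(truth, n_spots, seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), n_spots >= 1)
  if (!is.null(seed)) set.seed(seed)
  nmax <- length(truth$alpha_true)
  n_true <- sample.int(nmax, n_spots, replace = TRUE, prob = truth$alpha_true)
  draws <- rbrightness(sum(n_true), truth$monomer_brightness_mean,
                       truth$monomer_brightness_cv)
  idx <- rep.int(seq_len(n_spots), n_true)
  brightness <- as.numeric(tapply(draws, idx, sum))
  data.frame(brightness = brightness, n_true = n_true)
}

#' Simulate a normalized FRAP recovery curve
#'
#' `I/I0 = m * (1 - exp(-t / tau))` plus additive Gaussian noise: the
#' saturating single-exponential recovery of the bleached-region intensity,
#' whose plateau is the mobile fraction m.
#'
#' @param mobile_fraction m in `[0, 1]`.
#' @param tau recovery time constant (s, > 0).
#' @param timestamps times after the end of the bleach pulse (s).
#' @param noise_sd additive noise SD on the normalized intensity (>= 0).
#' @param seed optional integer seed.
#' @return data.frame with columns `t` (s) and `intensity` (I/I0).
#' @export
simulate_frap_curve <- function(mobile_fraction, tau, timestamps,
                                noise_sd = 0, seed = NULL) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  y <- mobile_fraction * (1 - exp(-timestamps / tau))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(t = as.numeric(timestamps), intensity = y)
}

#' Simulate 2-D Brownian trajectories
#'
#' Per-step displacements are independent zero-mean Gaussians with variance
#' `2 * D * dt` per axis.
#'
#' @param D diffusion coefficient (um^2/s, >= 0).
#' @param dt frame interval (s, > 0).
#' @param n_steps steps per track (positions per track = `n_steps + 1`).
#' @param n_tracks number of tracks.
#' @param seed optional integer seed.
#' @return data.frame with columns `track_id`, `t` (s), `x`, `y` (um);
#'   each track starts at the origin.
#' @export
simulate_trajectories <- function(D, dt, n_steps, n_tracks = 1, seed = NULL) {
  stopifnot(D >= 0, dt > 0, n_steps >= 1, n_tracks >= 1)
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  one <- function(id) {
    dx <- stats::rnorm(n_steps, 0, sd_step)
    dy <- stats::rnorm(n_steps, 0, sd_step)
    data.frame(track_id = id, t = (0:n_steps) * dt,
               x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
  }
  do.call(rbind, lapply(seq_len(n_tracks), one))
}

#' Create a complex population with per-subunit fluorophore labels
#'
#' Internal building block of the TOCCSL simulators: a table of subunits,
#' grouped into complexes whose sizes follow `alpha_true`, each subunit
#' carrying an active-fluorophore flag.
#'
#' @param n_complexes number of complexes.
#' @param alpha_true complex-size fractions.
#' @param labeling_fraction probability a subunit is fluorescent.
#' @param seed optional integer seed.
#' @return data.frame with columns `complex_id`, `size`, `fluorescent`.
#' @export
complex_population <- function(n_complexes, alpha_true,
                               labeling_fraction = 1, seed = NULL) {
  stopifnot(n_complexes >= 1)
  if (any(alpha_true < 0) || abs(sum(alpha_true) - 1) > 1e-12) {
    stop("alpha_true must be non-negative and sum to 1 (within 1e-12)")
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample.int(length(alpha_true), n_complexes, replace = TRUE,
                      prob = alpha_true)
  n_sub <- sum(sizes)
  fl <- if (labeling_fraction >= 1) rep(TRUE, n_sub) else
    stats::runif(n_sub) < labeling_fraction
  data.frame(complex_id = rep.int(seq_len(n_complexes), sizes),
             size = rep.int(sizes, sizes),
             fluorescent = fl)
}

#' Exchange subunits between complexes
#'
#' Models transient versus stable interaction: subunits swap between
#' complexes of the same size at a Poisson rate. `exchange_rate = 0` leaves
#' every label attached to its original partners; `exchange_rate * elapsed`
#' much greater than 1 randomizes the pairing completely, i.e. fluorescent
#' subunits are assigned to complexes binomially at the global unbleached
#' fraction. Complex sizes (and the total fluorophore count) are conserved.
#'
#' @param population data.frame from [complex_population()] (columns
#'   `complex_id`, `size`, `fluorescent`); the `fluorescent` flags typically
#'   carry bleach history.
#' @param exchange_rate per-subunit exchange rate (1/s, >= 0; `Inf` allowed).
#' @param elapsed elapsed time (s, >= 0).
#' @param seed optional integer seed.
#' @return The relabeled population (same shape, same `complex_id` order).
#' @export
apply_subunit_exchange <- function(population, exchange_rate, elapsed,
                                   seed = NULL) {
  stopifnot(is.data.frame(population),
            all(c("complex_id", "size", "fluorescent") %in% names(population)))
  if (is.na(exchange_rate) || exchange_rate < 0) {
    stop("exchange_rate must be non-negative")
  }
  stopifnot(elapsed >= 0)
  if (exchange_rate == 0 || elapsed == 0) return(population)
  if (!is.null(seed)) set.seed(seed)
  pop <- population
  # expected number of pairwise swap events
  n_sub <- nrow(pop)
  intensity <- exchange_rate * elapsed * n_sub / 2
  for (sz in unique(pop$size)) {
    if (sz < 1) next
    rows <- which(pop$size == sz)
    n_complex_sz <- length(rows) / sz
    if (n_complex_sz < 2) next
    share <- intensity * length(rows) / n_sub
    if (!is.finite(share) || share > 20 * length(rows)) {
      # effectively complete mixing: one global shuffle within the size class
      pop$fluorescent[rows] <- sample(pop$fluorescent[rows])
    } else {
      n_events <- stats::rpois(1, share)
      for (e in seq_len(n_events)) {
        ij <- sample(rows, 2)
        tmp <- pop$fluorescent[ij[1]]
        pop$fluorescent[ij[1]] <- pop$fluorescent[ij[2]]
        pop$fluorescent[ij[2]] <- tmp
      }
    }
  }
  pop
}

#' Spot-level composition of the visible population
#'
#' Summarizes a labeled population as the apparent oligomer distribution a
#' TOCCSL recovery image would report: a complex is visible if it carries at
#' least one active fluorophore, and its apparent order is the number of
#' active fluorophores.
#'
#' @param population data.frame from [complex_population()].
#' @param n_max pad the returned fraction vector to this length (default:
#'   largest complex size present).
#' @return Named numeric vector of visible-spot fractions by apparent order.
#' @export
visible_composition <- function(population, n_max = NULL) {
  k <- tapply(population$fluorescent, population$complex_id, sum)
  k <- k[k >= 1]
  if (is.null(n_max)) n_max <- max(population$size)
  if (length(k) == 0) return(stats::setNames(rep(NA_real_, n_max), seq_len(n_max)))
  tab <- tabulate(k, nbins = n_max)
  stats::setNames(tab / sum(tab), seq_len(n_max))
}
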