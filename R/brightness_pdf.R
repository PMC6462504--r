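#' Brightness probability density on a uniform grid
#'
#' Container for a probability density over single-spot brightness B
#' (photons). All densities in the package — the empirical monomer density
#' rho_1(B), its n-fold autoconvolutions rho_N(B), and fitted mixtures —
#' live on a uniform grid so that convolution, interpolation and moments are
#' well defined and cheap.
#'
#' @param grid numeric vector of brightness values (photons), uniformly
#'   spaced, non-negative and increasing.
#' @param density numeric vector of density values (per photon) on `grid`.
#'   Must be non-negative; it is renormalized to trapezoidal integral 1.
#' @param provenance one of `"monomer-empirical"`, `"autoconvolved-N"`,
#'   `"mixture-fit"`, or a free-form label.
#' @return An object of class `brightness_pdf` with elements `grid`,
#'   `density`, `provenance`.
#' @examples
#' g <- seq(0, 400, length.out = 1024)
#' rho <- brightness_pdf(g, dlnorm(g, log(100), 0.3))
#' pdf_mean(rho)
#' @export
brightness_pdf <- function(grid, density, provenance = "monomer-empirical") {
  if (!is.numeric(grid) || !is.numeric(density) ||
      length(grid) != length(density) || length(grid) < 8) {
    stop("grid and density must be numeric vectors of equal length >= 8")
  }
  h <- diff(grid)
  if (any(h <= 0)) stop("grid must be strictly increasing")
  if ((max(h) - min(h)) > 1e-8 * mean(h)) stop("grid spacing must be uniform")
  if (min(density) < -1e-10 * max(abs(density))) {
    stop("density must be non-negative")
  }
  density <- pmax(density, 0)
  mass <- pracma::trapz(grid, density)
  if (!is.finite(mass) || mass <= 0) stop("density has zero or non-finite mass")
  structure(
    list(grid = as.numeric(grid), density = as.numeric(density) / mass,
         provenance = provenance),
    class = "brightness_pdf"
  )
}

#' @export
print.brightness_pdf <- function(x, ...) {
  cat(sprintf(
    "<brightness_pdf> %s | %d grid points on [%.3g, %.3g] photons | mean %.4g, sd %.4g\n",
    x$provenance, length(x$grid), x$grid[1], x$grid[length(x$grid)],
    pdf_mean(x), sqrt(pdf_var(x))))
  invisible(x)
}

#' Moments of a brightness PDF
#'
#' Trapezoidal-rule mean and variance of a [brightness_pdf].
#' @param rho a `brightness_pdf`.
#' @return A scalar.
#' @export
pdf_mean <- function(rho) {
  stopifnot(inherits(rho, "brightness_pdf"))
  pracma::trapz(rho$grid, rho$grid * rho$density)
}

#' @rdname pdf_mean
#' @export
pdf_var <- function(rho) {
  m <- pdf_mean(rho)
  pracma::trapz(rho$grid, (rho$grid - m)^2 * rho$density)
}

# cumulative distribution on the grid (trapezoidal), used for sampling
pdf_cdf <- function(rho) {
  d <- rho$density
  h <- rho$grid[2] - rho$grid[1]
  cdf <- c(0, cumsum((d[-length(d)] + d[-1]) / 2 * h))
  cdf / cdf[length(cdf)]
}

#' Draw samples from a brightness PDF
#'
#' Inverse-CDF sampling on the density's grid (linear interpolation of the
#' trapezoidal CDF).
#'
#' @param rho a `brightness_pdf`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_pdf <- function(rho, n, seed = NULL) {
  stopifnot(inherits(rho, "brightness_pdf"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cdf <- pdf_cdf(rho)
  # make the CDF strictly increasing so approx() is invertible on flats
  eps <- seq_along(cdf) * 1e-12
  stats::approx(cdf + eps, rho$grid, xout = stats::runif(n), rule = 2)$y
}

#' Interpolate a brightness PDF at arbitrary points
#'
#' @param rho a `brightness_pdf`.
#' @param x points (photons) at which to evaluate; outside the grid the
#'   density is 0.
#' @return Numeric vector of density values.
#' @export
pdf_at <- function(rho, x) {
  stats::approx(rho$grid, rho$density, xout = x, yleft = 0, yright = 0)$y
}

#' n-fold autoconvolution of the monomer brightness density
#'
#' The brightness of an N-mer carrying N independent active fluorophores is
#' the sum of N independent single-fluorophore brightnesses, so its density
#' rho_N(B) is the N-fold convolution of the monomer density rho_1(B). The
#' convolution is computed by FFT on the common grid with explicit
#' zero-padding (no wrap-around); the result is truncated back to the input
#' grid and renormalized. If more than `max_mass_loss` probability mass of
#' the N-fold support would fall beyond the grid, the grid is too short and
#' an error is raised.
#'
#' @param rho1 monomer `brightness_pdf`; its grid must start at 0.
#' @param n convolution order N >= 1 (`n = 1` returns `rho1` unchanged).
#' @param max_mass_loss maximal tolerated truncated mass (default `1e-4`).
#' @return A `brightness_pdf` with provenance `"autoconvolved-N"`.
#' @examples
#' g <- seq(0, 800, length.out = 2048)
#' rho1 <- brightness_pdf(g, dlnorm(g, log(100), 0.34))
#' rho2 <- autoconvolve(rho1, 2)
#' all.equal(pdf_mean(rho2), 2 * pdf_mean(rho1), tolerance = 1e-3)
#' @export
autoconvolve <- function(rho1, n, max_mass_loss = 1e-4) {
  stopifnot(inherits(rho1, "brightness_pdf"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  if (n == 1L) return(rho1)
  ng <- length(rho1$grid)
  h <- rho1$grid[2] - rho1$grid[1]
  if (abs(rho1$grid[1]) > h / 2) {
    stop("autoconvolution requires a grid starting at 0")
  }
  # full linear convolution length, padded to avoid circular wrap-around
  full_len <- n * (ng - 1L) + 1L
  pad <- stats::nextn(full_len, 2)
  fv <- stats::fft(c(rho1$density, rep(0, pad - ng)))
  conv <- Re(stats::fft(fv^n, inverse = TRUE)) / pad * h^(n - 1L)
  conv <- pmax(conv[seq_len(full_len)], 0)
  kept <- conv[seq_len(ng)]
  lost <- h * sum(conv[-seq_len(ng)])
  if (lost > max_mass_loss) {
    stop(sprintf(
      "grid too short for %d-fold autoconvolution: %.3g probability mass beyond grid (limit %.3g)",
      n, lost, max_mass_loss))
  }
  brightness_pdf(rho1$grid, kept, provenance = sprintf("autoconvolved-%d", n))
}

#' Brightness densities for N-mers up to N_max
#'
#' @param rho1 monomer `brightness_pdf`.
#' @param n_max largest oligomer order.
#' @return List of `brightness_pdf`s, element N being rho_N.
#' @export
nmer_pdfs <- function(rho1, n_max) {
  stopifnot(n_max >= 1)
  lapply(seq_len(n_max), function(n) autoconvolve(rho1, n))
}

#' Kernel-density estimate of the monomer brightness PDF
#'
#' Builds rho_1(B) from calibration spot brightnesses (cells extensively
#' photobleached so that each complex carries at most one active
#' fluorophore). Gaussian kernel with Silverman's bandwidth on a uniform
#' grid; the grid extends far enough to hold the N_max-fold autoconvolution
#' support.
#'
#' @param samples calibration brightness values (photons), all non-negative.
#' @param n_grid number of grid points (default 2048).
#' @param grid_max upper grid limit; default `n_max` times the 99.9th sample
#'   percentile.
#' @param n_max largest oligomer order the grid must support (default 5).
#' @param bw kernel bandwidth; default Silverman's rule (`"nrd0"`).
#' @return A `brightness_pdf` with provenance `"monomer-empirical"`.
#' @export
estimate_monomer_pdf <- function(samples, n_grid = 2048, grid_max = NULL,
                                 n_max = 5, bw = "nrd0") {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("calibration samples contain NA")
  if (any(samples < 0)) stop("calibration brightness samples must be non-negative")
  if (length(samples) < 20) {
    stop("at least 20 calibration samples are required to estimate rho_1")
  }
  if (length(samples) < 200) {
    warning("fewer than 200 calibration samples; rho_1 estimate may be unstable")
  }
  if (is.null(grid_max)) {
    grid_max <- n_max * as.numeric(stats::quantile(samples, 0.999, names = FALSE))
  }
  if (grid_max <= max(samples)) grid_max <- 1.05 * max(samples) * n_max
  if (identical(bw, "nrd0") && stats::sd(samples) == 0) {
    bw <- max(0.01 * mean(samples), 1e-6)  # degenerate (all-equal) input
  }
  kd <- stats::density(samples, bw = bw, from = 0, to = grid_max, n = n_grid)
  brightness_pdf(kd$x, kd$y, provenance = "monomer-empirical")
}
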