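# Oligomer-fraction deconvolution: fit the observed single-spot brightness
# distribution rho(B) as a non-negative linear combination of the n-mer
# densities rho_N(B), Sum_N alpha_N * rho_N(B), with Sum alpha_N = 1.

# component matrix: density of each rho_N at each sample
.component_matrix <- function(samples, components) {
  P <- vapply(components, function(r) pdf_at(r, samples),
              numeric(length(samples)))
  P <- matrix(P, nrow = length(samples))
  pmax(P, 1e-300)
}

# EM for simplex mixture weights with fixed components; the log-likelihood
# is concave in alpha, so EM converges to the global constrained maximum.
.em_weights <- function(P, tol = 1e-9, max_iter = 5000) {
  K <- ncol(P)
  a <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    m <- drop(P %*% a)
    a_new <- a * colMeans(P / m)
    a_new <- a_new / sum(a_new)
    ll <- sum(log(drop(P %*% a_new)))
    if (max(abs(a_new - a)) < tol && ll - ll_old < 1e-10) {
      a <- a_new
      break
    }
    a <- a_new
    ll_old <- ll
  }
  list(alpha = a, loglik = sum(log(drop(P %*% a))), iterations = it)
}

# binned non-negative least squares on the empirical density (cross-check
# fitting mode); alpha renormalized to the simplex afterwards.
.ls_weights <- function(samples, components, n_bins = 128) {
  grid <- components[[1]]$grid
  lim <- range(samples)
  breaks <- seq(lim[1], lim[2], length.out = n_bins + 1)
  hst <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  mids <- hst$mids
  A <- vapply(components, function(r) pdf_at(r, mids), numeric(length(mids)))
  a <- pracma::lsqnonneg(matrix(A, nrow = length(mids)), hst$density)$x
  if (sum(a) <= 0) stop("least-squares fit degenerate: all weights zero")
  list(alpha = a / sum(a), loglik = NA_real_, iterations = NA_integer_)
}

#' Fit the oligomer-fraction mixture to spot brightnesses
#'
#' Estimates the fractions alpha_N of visible N-mers by fitting the
#' observed brightness distribution as `rho(B) = Sum_N alpha_N rho_N(B)`
#' with `alpha_N >= 0`, `Sum alpha_N = 1`. The default criterion is maximum
#' likelihood of the samples under the mixture density (EM on the simplex;
#' deterministic given samples and grid). `method = "ls"` instead fits the
#' binned empirical density by non-negative least squares — a cross-check
#' mode that should agree with ML within bootstrap error.
#'
#' @param samples spot brightness values (photons), or a data.frame with a
#'   `brightness` column.
#' @param rho1 monomer `brightness_pdf`; ignored if `components` given.
#' @param n_max largest oligomer order fitted (default 5).
#' @param components optional precomputed list of rho_N (from
#'   [nmer_pdfs()]); overrides `rho1`/`n_max`.
#' @param method `"ml"` (maximum likelihood, default) or `"ls"`.
#' @param tol EM convergence tolerance on alpha.
#' @param max_iter EM iteration cap.
#' @return An object of class `mixture_result`: `alpha`, `alpha_se` (NA
#'   until [bootstrap_alpha()] is run), `n_max`, `n_spots`,
#'   `residual_norm` (L2 distance between fitted and binned empirical
#'   density), `loglik`, `method`, `conditioning_warning`.
#' @export
fit_mixture <- function(samples, rho1 = NULL, n_max = 5, components = NULL,
                        method = c("ml", "ls"), tol = 1e-9, max_iter = 5000) {
  method <- match.arg(method)
  if (is.data.frame(samples)) samples <- samples$brightness
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("need at least 2 brightness samples")
  if (any(samples < 0)) stop("brightness samples must be non-negative")
  if (is.null(components)) {
    if (is.null(rho1)) stop("either rho1 or components must be supplied")
    if (n_max < 1) stop("n_max must be >= 1")
    components <- nmer_pdfs(rho1, n_max)
  }
  n_max <- length(components)
  cond_warn <- FALSE
  cv1 <- sqrt(pdf_var(components[[1]])) / pdf_mean(components[[1]])
  if (is.finite(cv1) && cv1 < 0.05 && n_max > 1) {
    cond_warn <- TRUE
    warning("monomer brightness CV < 0.05: mixture components are nearly collinear; fractions may be ill-conditioned")
  }
  fit <- if (method == "ml") {
    .em_weights(.component_matrix(samples, components), tol, max_iter)
  } else {
    .ls_weights(samples, components)
  }
  # goodness of fit: L2 distance between mixture and binned empirical pdf
  lim <- range(samples)
  breaks <- seq(lim[1], lim[2], length.out = 65)
  hst <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  model <- drop(vapply(components, function(r) pdf_at(r, hst$mids),
                       numeric(64)) %*% fit$alpha)
  resid <- sqrt(sum((hst$density - model)^2) * diff(breaks[1:2]))
  structure(
    list(alpha = fit$alpha, alpha_se = rep(NA_real_, n_max), n_max = n_max,
         n_spots = length(samples), residual_norm = resid,
         loglik = fit$loglik, iterations = fit$iterations, method = method,
         conditioning_warning = cond_warn, components = components),
    class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("<mixture_result> %s fit of %d spots, N_max = %d\n",
              x$method, x$n_spots, x$n_max))
  se <- ifelse(is.na(x$alpha_se), "", sprintf(" +/- %.3f", x$alpha_se))
  for (n in seq_len(x$n_max)) {
    cat(sprintf("  alpha_%d = %.3f%s\n", n, x$alpha[n], se[n]))
  }
  cat(sprintf("  residual L2 = %.4g\n", x$residual_norm))
  invisible(x)
}

#' Bootstrap standard errors of the oligomer fractions
#'
#' Random subsamples containing `subsample_fraction` of the spots (drawn
#' without replacement) are re-fitted `n_reps` times; the reported error for
#' each oligomer order is the standard deviation over replicates divided by
#' sqrt(2) — the half-sample subsampling estimate of the full-sample
#' standard error.
#'
#' @param samples brightness values (photons) or data.frame with
#'   `brightness`.
#' @param components list of rho_N densities (from [nmer_pdfs()]).
#' @param n_reps replicates (default 100).
#' @param subsample_fraction fraction per replicate (default 0.5).
#' @param seed integer seed.
#' @param min_fit_n smallest subsample that is still fitted; smaller (or
#'   failing) replicates are skipped and counted, more than 10 percent
#'   skips is an error.
#' @param method fitting criterion, as in [fit_mixture()].
#' @return Numeric vector `alpha_se` with attributes `replicates` (matrix
#'   of replicate alphas) and `n_skipped`.
#' @export
bootstrap_alpha <- function(samples, components, n_reps = 100,
                            subsample_fraction = 0.5, seed = NULL,
                            min_fit_n = 20, method = "ml") {
  if (is.data.frame(samples)) samples <- samples$brightness
  samples <- as.numeric(samples)
  if (!is.null(seed)) set.seed(seed)
  n <- length(samples)
  m <- floor(n * subsample_fraction)
  K <- length(components)
  P <- .component_matrix(samples, components)
  reps <- matrix(NA_real_, n_reps, K)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, m)
    if (m < min_fit_n) { skipped <- skipped + 1L; next }
    a <- tryCatch({
      if (method == "ml") .em_weights(P[idx, , drop = FALSE],
                                      tol = 1e-8, max_iter = 2000)$alpha
      else .ls_weights(samples[idx], components)$alpha
    }, error = function(e) NULL)
    if (is.null(a)) { skipped <- skipped + 1L; next }
    reps[r, ] <- a
  }
  if (skipped > 0.1 * n_reps) {
    stop(sprintf("%d of %d bootstrap replicates failed", skipped, n_reps))
  }
  se <- apply(reps, 2, stats::sd, na.rm = TRUE) / sqrt(2)
  attr(se, "replicates") <- reps
  attr(se, "n_skipped") <- skipped
  se
}

#' Fit the mixture with bootstrap errors attached
#'
#' @inheritParams fit_mixture
#' @inheritParams bootstrap_alpha
#' @return A `mixture_result` with `alpha_se` filled in.
#' @export
fit_mixture_boot <- function(samples, rho1 = NULL, n_max = 5,
                             components = NULL, n_reps = 100,
                             subsample_fraction = 0.5, seed = NULL,
                             method = "ml") {
  if (is.null(components)) components <- nmer_pdfs(rho1, n_max)
  res <- fit_mixture(samples, components = components, method = method)
  se <- bootstrap_alpha(samples, components, n_reps = n_reps,
                        subsample_fraction = subsample_fraction,
                        seed = seed, method = method)
  res$alpha_se <- as.numeric(se)
  res
}

#' Minimal detectable oligomer fraction by simulation
#'
#' Quantifies the detection sensitivity of the brightness analysis: for
#' each order N, the smallest injected fraction alpha_N that is recovered
#' above twice its bootstrap standard error in at least `power` of
#' simulated experiments with `n_spots` spots. Fractions below the returned
#' value are below the detection sensitivity at that sample size.
#'
#' @param rho1 monomer `brightness_pdf`.
#' @param n_max largest order probed.
#' @param n_spots spots per simulated experiment.
#' @param alpha_background composition of the remaining (1 - alpha_N) mass
#'   (default pure monomer).
#' @param fraction_grid candidate injected fractions, ascending.
#' @param n_sims simulated experiments per candidate fraction.
#' @param n_boot bootstrap replicates per fit (kept small here; this is a
#'   power computation, not a reported error bar).
#' @param power required detection probability (default 0.95).
#' @param orders which N to probe (default `2:n_max`).
#' @param seed integer seed.
#' @return data.frame with columns `n` (oligomer order),
#'   `min_detectable_fraction` (NA if no grid value reaches the power), and
#'   attribute `power_table` with the per-fraction detection rates.
#' @export
detection_sensitivity <- function(rho1, n_max = 5, n_spots = 10000,
                                  alpha_background = 1,
                                  fraction_grid = c(0.005, 0.01, 0.02, 0.05,
                                                    0.1, 0.2, 0.35),
                                  n_sims = 20, n_boot = 30, power = 0.95,
                                  orders = NULL, seed = NULL) {
  stopifnot(inherits(rho1, "brightness_pdf"), n_spots >= 10, n_max >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(orders)) orders <- 2:n_max
  components <- nmer_pdfs(rho1, n_max)
  bg <- alpha_background / sum(alpha_background)
  bg <- c(bg, rep(0, n_max - length(bg)))
  pw <- list()
  out <- data.frame(n = orders, min_detectable_fraction = NA_real_)
  for (N in orders) {
    for (f in sort(fraction_grid)) {
      alpha <- bg * (1 - f)
      alpha[N] <- alpha[N] + f
      hits <- 0L
      for (s in seq_len(n_sims)) {
        comp_idx <- sample.int(n_max, n_spots, replace = TRUE, prob = alpha)
        smp <- numeric(n_spots)
        for (k in unique(comp_idx)) {
          sel <- comp_idx == k
          smp[sel] <- sample_pdf(components[[k]], sum(sel))
        }
        fit <- fit_mixture(smp, components = components)
        se <- bootstrap_alpha(smp, components, n_reps = n_boot)
        if (fit$alpha[N] >= 2 * se[N]) hits <- hits + 1L
      }
      pw[[length(pw) + 1]] <- data.frame(n = N, fraction = f,
                                         detection_rate = hits / n_sims)
      if (hits / n_sims >= power) {
        out$min_detectable_fraction[out$n == N] <- f
        break
      }
    }
  }
  attr(out, "power_table") <- do.call(rbind, pw)
  out
}

#' Write a mixture result to JSON
#'
#' @param x a `mixture_result`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mixture_result <- function(x, path) {
  stopifnot(inherits(x, "mixture_result"))
  jsonlite::write_json(
    list(alpha = x$alpha, alpha_se = x$alpha_se, n_max = x$n_max,
         n_spots = x$n_spots, residual_norm = x$residual_norm,
         loglik = x$loglik, method = x$method),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Plot the brightness-PDF decomposition
#'
#' Observed brightness density (histogram), fitted mixture and the weighted
#' n-mer contributions — the standard decomposition figure of the method.
#'
#' @param samples brightness values used in the fit.
#' @param fit a `mixture_result` (with `components` retained).
#' @param n_bins histogram bins.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_mixture <- function(samples, fit, n_bins = 60, ...) {
  stopifnot(inherits(fit, "mixture_result"))
  if (is.data.frame(samples)) samples <- samples$brightness
  grid <- fit$components[[1]]$grid
  mix <- Reduce(`+`, Map(function(a, r) a * r$density, fit$alpha,
                         fit$components))
  graphics::hist(samples, breaks = n_bins, freq = FALSE, col = "grey90",
                 border = "grey70", xlab = "single-spot brightness B (photons)",
                 ylab = "probability density", main = "", ...)
  graphics::lines(grid, mix, col = "red", lwd = 2, lty = 2)
  for (n in seq_len(fit$n_max)) {
    if (fit$alpha[n] > 1e-3) {
      graphics::lines(grid, fit$alpha[n] * fit$components[[n]]$density,
                      col = "blue")
    }
  }
  invisible(NULL)
}
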