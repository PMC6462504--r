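test_that("pure-monomer samples are fitted as pure monomer", {
  rho1 <- calibration_rho1()
  s <- simulate_brightness_samples(ground_truth(alpha_true = 1, seed = 81), 5000)
  fit <- fit_mixture(s, rho1)
  expect_gt(fit$alpha[1], 0.98)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-8)
})

test_that("the 55/35/10 membrane regime is recovered within 3 points", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 5)
  alphas <- sapply(c(82, 83), function(seed) {
    s <- simulate_brightness_samples(membrane_truth(seed = seed), 1e4)
    fit_mixture(s, components = comps)$alpha
  })
  a <- rowMeans(alphas)
  expect_lt(abs(a[1] - 0.55), 0.03)
  expect_lt(abs(a[2] - 0.35), 0.03)
  expect_lt(abs(a[3] - 0.10), 0.03)
})

test_that("the EM solver equals exhaustive-search maximum likelihood", {
  # 3-point discrete brightness alphabet, realised as narrow densities
  g <- seq(0, 60, length.out = 1024)
  atom <- function(mu) brightness_pdf(g, dnorm(g, mu, 0.6))
  comps <- list(atom(10), atom(20), atom(30))
  set.seed(84)
  truth <- c(0.5, 0.2, 0.3)
  z <- sample.int(3, 600, replace = TRUE, prob = truth)
  s <- c(10, 20, 30)[z] + rnorm(600, 0, 0.6)
  fit <- fit_mixture(s, components = comps)

  # oracle: coarse simplex scan, then local refinement, on the same
  # component likelihoods but by brute force
  P <- vapply(comps, function(r) pdf_at(r, s), numeric(length(s)))
  P <- pmax(P, 1e-300)
  scan <- function(a1s, a2s) {
    best <- c(NA, NA); best_ll <- -Inf
    for (a1 in a1s) for (a2 in a2s) {
      if (a1 + a2 > 1 + 1e-12) next
      ll <- sum(log(P %*% c(a1, a2, max(1 - a1 - a2, 0))))
      if (ll > best_ll) { best_ll <- ll; best <- c(a1, a2) }
    }
    best
  }
  co <- scan(seq(0, 1, by = 0.005), seq(0, 1, by = 0.005))
  fine <- scan(seq(max(0, co[1] - 0.006), min(1, co[1] + 0.006), by = 2e-4),
               seq(max(0, co[2] - 0.006), min(1, co[2] + 0.006), by = 2e-4))
  oracle <- c(fine, 1 - sum(fine))
  expect_lt(max(abs(fit$alpha - oracle)), 1e-3)
})

test_that("binned least squares agrees with maximum likelihood", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 5)
  s <- simulate_brightness_samples(membrane_truth(seed = 85), 8000)
  ml <- fit_mixture(s, components = comps)
  ls <- fit_mixture(s, components = comps, method = "ls")
  se <- bootstrap_alpha(s, comps, n_reps = 60, seed = 86)
  expect_lt(max(abs(ml$alpha - ls$alpha) / pmax(2 * se, 0.02)), 1)
})

test_that("near-degenerate monomer density triggers a conditioning warning", {
  set.seed(87)
  smp <- rnorm(2000, 100, 2)  # CV 0.02
  rho1 <- estimate_monomer_pdf(smp)
  expect_warning(fit_mixture(c(rnorm(500, 100, 2), rnorm(100, 200, 3)), rho1),
                 "collinear|ill-conditioned")
})

test_that("the fit is invariant under sample permutation", {
  rho1 <- calibration_rho1()
  s <- simulate_brightness_samples(membrane_truth(seed = 88), 3000)$brightness
  f1 <- fit_mixture(s, rho1, n_max = 3)
  set.seed(89)
  f2 <- fit_mixture(sample(s), rho1, n_max = 3)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
})

test_that("bootstrap errors shrink like n^(-1/2) and are reproducible", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 3)
  s_small <- simulate_brightness_samples(membrane_truth(seed = 90), 1000)
  s_large <- simulate_brightness_samples(membrane_truth(seed = 91), 4000)
  se_small <- bootstrap_alpha(s_small, comps, n_reps = 60, seed = 92)
  se_large <- bootstrap_alpha(s_large, comps, n_reps = 60, seed = 93)
  ratio <- se_small[2] / se_large[2]   # expected ~ sqrt(4) = 2
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.3)
  expect_identical(as.numeric(bootstrap_alpha(s_small, comps, n_reps = 20, seed = 5)),
                   as.numeric(bootstrap_alpha(s_small, comps, n_reps = 20, seed = 5)))
})

test_that("dimer-fraction bootstrap SE is below 0.05 in the membrane regime", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 5)
  s <- simulate_brightness_samples(membrane_truth(seed = 94), 1e4)
  se <- bootstrap_alpha(s, comps, n_reps = 100, seed = 95)
  expect_lt(se[2], 0.05)
  expect_gt(se[2], 0)
})

test_that("bootstrap fails loudly when subsamples are too small to fit", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 2)
  s <- simulate_brightness_samples(membrane_truth(seed = 96), 30)
  expect_error(bootstrap_alpha(s, comps, n_reps = 20, min_fit_n = 20),
               "replicates failed")
})

test_that("parametric bootstrap closure: refitting fitted mixtures is stable", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 3)
  s <- simulate_brightness_samples(membrane_truth(seed = 97), 6000)
  fit <- fit_mixture_boot(s, components = comps, n_reps = 60, seed = 98)
  # draw new samples from the *fitted* mixture and refit
  set.seed(99)
  z <- sample.int(3, 6000, replace = TRUE, prob = fit$alpha)
  s2 <- numeric(6000)
  for (k in 1:3) s2[z == k] <- sample_pdf(comps[[k]], sum(z == k))
  fit2 <- fit_mixture(s2, components = comps)
  expect_lt(max(abs(fit2$alpha - fit$alpha) / pmax(3 * fit$alpha_se, 0.02)), 1)
})

test_that("mixture PDFs stay normalized through every transformation", {
  rho1 <- calibration_rho1()
  comps <- nmer_pdfs(rho1, 5)
  s <- simulate_brightness_samples(membrane_truth(seed = 100), 2000)
  fit <- fit_mixture(s, components = comps)
  for (r in comps) {
    expect_equal(pracma::trapz(r$grid, r$density), 1, tolerance = 1e-6)
  }
  mix <- Reduce(`+`, Map(function(a, r) a * r$density, fit$alpha, comps))
  expect_equal(pracma::trapz(rho1$grid, mix), 1, tolerance = 1e-6)
})

test_that("an injected 35% dimer fraction is reliably detected", {
  rho1 <- calibration_rho1()
  sens <- detection_sensitivity(rho1, n_max = 3, n_spots = 5000,
                                fraction_grid = 0.35, n_sims = 8,
                                n_boot = 16, orders = 2, seed = 101)
  expect_equal(sens$min_detectable_fraction[1], 0.35)
  pt <- attr(sens, "power_table")
  expect_gte(pt$detection_rate[pt$fraction == 0.35], 0.95)
})

test_that("a 0.5% pentamer fraction at n = 1000 is not reliably detected", {
  rho1 <- calibration_rho1()
  sens <- detection_sensitivity(rho1, n_max = 5, n_spots = 1000,
                                fraction_grid = 0.005, n_sims = 8,
                                n_boot = 16, orders = 5, seed = 102)
  pt <- attr(sens, "power_table")
  # a handful of bright outliers can flag a pentamer component in some
  # realisations, but detection falls well short of the 95% reliability bar
  expect_lt(pt$detection_rate[1], 0.95)
  expect_true(is.na(sens$min_detectable_fraction[1]))
})

test_that("sensitivity improves with the number of spots", {
  rho1 <- calibration_rho1()
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.35)
  s_small <- detection_sensitivity(rho1, n_max = 2, n_spots = 600,
                                   fraction_grid = grid, n_sims = 8,
                                   n_boot = 16, orders = 2, seed = 103)
  s_large <- detection_sensitivity(rho1, n_max = 2, n_spots = 8000,
                                   fraction_grid = grid, n_sims = 8,
                                   n_boot = 16, orders = 2, seed = 104)
  expect_lte(s_large$min_detectable_fraction[1],
             s_small$min_detectable_fraction[1])
})
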