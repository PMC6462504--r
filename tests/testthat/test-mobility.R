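test_that("FRAP fit inverts the generator exactly on noiseless curves", {
  tt <- seq(0.5, 60, by = 0.5)
  fit <- fit_frap(simulate_frap_curve(0.78, 8, tt))
  expect_equal(fit$mobile_fraction, 0.78, tolerance = 1e-6)
  expect_equal(fit$tau, 8, tolerance = 1e-6)
  # inverse property over the parameter plane
  for (m in c(0.2, 0.55, 1)) {
    for (tau in c(2, 20, 80)) {
      f <- fit_frap(simulate_frap_curve(m, tau, seq(0.5, 4 * tau, length.out = 60)))
      expect_equal(f$mobile_fraction, m, tolerance = 1e-5)
      expect_equal(f$tau, tau, tolerance = 1e-4)
    }
  }
})

test_that("an immobile field is reported as mobile fraction 0 and flagged", {
  tt <- seq(0.5, 30, by = 0.5)
  fit <- fit_frap(simulate_frap_curve(0, 10, tt, noise_sd = 0.005, seed = 110))
  expect_identical(fit$mobile_fraction, 0)
  expect_true("tau_unidentifiable" %in% fit$flags)
})

test_that("an 11-cell FRAP ensemble recovers the 78% mobile fraction", {
  tt <- seq(0.5, 40, by = 0.5)
  m_hat <- vapply(1:11, function(cell) {
    curve <- simulate_frap_curve(0.78, 8, tt, noise_sd = 0.03, seed = 110 + cell)
    fit_frap(curve)$mobile_fraction
  }, numeric(1))
  expect_lt(abs(mean(m_hat) - 0.78), 0.10)
})

test_that("normalized FRAP stacks plateau at the mobile fraction", {
  cam <- camera_model(pixel_size = 0.5, field_of_view = c(40L, 40L),
                      psf_sigma = 0.25)
  tr <- ground_truth(surface_density = 50, diffusion_coeff = 1,
                     mobile_fraction = 0.78, seed = 112)
  stk <- simulate_frap_stack(tr, camera = cam,
                             bleach_region_um = c(6, 14, 6, 14),
                             timestamps = seq(1, 100, by = 2.5),
                             reservoir_margin_um = 25)
  curve <- normalize_frap(stk)
  expect_lt(curve$intensity[1], 0.35)        # starts near zero
  fit <- fit_frap(curve)
  expect_lt(abs(fit$mobile_fraction - 0.78), 0.10)
})

test_that("control stacks give flat curves at 1 and 0", {
  cam <- camera_model(pixel_size = 0.5, field_of_view = c(32L, 32L),
                      psf_sigma = 0.25)
  tr <- ground_truth(surface_density = 50, diffusion_coeff = 0.5,
                     mobile_fraction = 0.78, seed = 113)
  unbleached <- normalize_frap(
    simulate_frap_stack(tr, camera = cam, timestamps = seq(1, 10),
                        skip_bleach = TRUE))
  expect_lt(max(abs(unbleached$intensity - 1)), 0.05)
  dark <- normalize_frap(
    simulate_frap_stack(ground_truth(surface_density = 50, diffusion_coeff = 0,
                                     mobile_fraction = 0, seed = 114),
                        camera = cam, timestamps = seq(1, 10),
                        bleach_all = TRUE))
  expect_lt(max(abs(dark$intensity)), 0.05)
})

test_that("the recovery curve is invariant to rescaling the signal", {
  cam <- camera_model(pixel_size = 0.5, field_of_view = c(32L, 32L),
                      psf_sigma = 0.25)
  tr <- ground_truth(surface_density = 50, diffusion_coeff = 1,
                     mobile_fraction = 0.6, seed = 115)
  stk <- simulate_frap_stack(tr, camera = cam, timestamps = seq(1, 40, by = 2))
  curve <- normalize_frap(stk)
  stk2 <- stk
  stk2$frames <- cam$offset + 3 * (stk$frames - cam$offset)
  curve2 <- normalize_frap(stk2)
  expect_equal(curve2$intensity, curve$intensity, tolerance = 1e-10)
})

test_that("MSD of Brownian tracks follows 4 D t_lag", {
  still <- simulate_trajectories(0, 0.01, 50, 20, seed = 120)
  expect_true(all(compute_msd(still, 3)$msd == 0))
  tr <- simulate_trajectories(0.118, 0.01, 100, 150, seed = 121)
  msd <- compute_msd(tr, 5)
  expect_lt(abs(msd$msd[1] - 4 * 0.118 * 0.01), 3 * msd$se[1])
  # monotone non-decreasing within the error bars
  expect_true(all(diff(msd$msd) > -3 * msd$se[-1]))
  expect_warning(compute_msd(simulate_trajectories(0.1, 0.01, 5, 2, seed = 1),
                             max_lag = 10), "truncating")
})

test_that("two-point diffusion fit reproduces the constructed fixture", {
  msd <- data.frame(lag = c(0.01, 0.02), msd = c(0.00572, 0.01044))
  fit <- fit_diffusion(msd)
  expect_equal(fit$D, 0.118, tolerance = 1e-9)
  expect_equal(fit$offset, 0.001, tolerance = 1e-9)
  neg <- fit_diffusion(data.frame(lag = c(0.01, 0.02), msd = c(0.02, 0.01)))
  expect_identical(neg$D, 0)
  expect_true("negative_slope_clipped" %in% neg$flags)
})

test_that("diffusion recovery is unbiased across two decades of D", {
  for (D in c(0.01, 0.1, 1)) {
    tr <- simulate_trajectories(D, 0.01, 100, 120, seed = round(1000 * D) + 7)
    fit <- fit_diffusion(compute_msd(tr, 3))
    expect_lt(abs(fit$D - D), 3 * fit$se_D)
    expect_lt(abs(fit$D - D) / D, 0.08)
  }
})

test_that("simulated tracking at D = 0.118 recovers D within 3 SE", {
  tr <- simulate_trajectories(0.118, 0.01, 100, 300, seed = 122)
  msd <- compute_msd(tr, 4)
  fit <- fit_diffusion(msd)
  expect_lt(abs(fit$D - 0.118), 3 * fit$se_D)
  expect_lt(fit$se_D, 0.004)
  expect_lt(abs(fit$offset), 3e-4)
})
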