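test_that("brightness samples have the closed-form mixture mean", {
  # pure monomer
  tr1 <- ground_truth(alpha_true = 1, seed = 21)
  s1 <- simulate_brightness_samples(tr1, 1e4)
  se1 <- stats::sd(s1$brightness) / sqrt(1e4)
  expect_lt(abs(mean(s1$brightness) - 100), 3 * se1)
  # 55/35/10 mixture: mean = (0.55 + 0.70 + 0.30) * 100
  tr <- membrane_truth(seed = 22)
  s <- simulate_brightness_samples(tr, 1e4)
  se <- stats::sd(s$brightness) / sqrt(1e4)
  expect_lt(abs(mean(s$brightness) - 155), 3 * se)
  # labels match the drawn stoichiometry
  expect_true(all(s$n_true %in% 1:3))
  expect_equal(mean(s$n_true == 2), 0.35, tolerance = 0.05)
})

test_that("zero-variance monomer brightness gives exact level sets", {
  tr <- ground_truth(alpha_true = c(0.55, 0.45), monomer_brightness_cv = 0,
                     seed = 23)
  s <- simulate_brightness_samples(tr, 2000)
  expect_setequal(unique(s$brightness), c(100, 200))
  expect_identical(s$brightness, 100 * s$n_true)
})

test_that("non-normalized oligomer fractions are rejected", {
  expect_error(ground_truth(alpha_true = c(0.5, 0.4)), "sum to 1")
  expect_error(ground_truth(alpha_true = c(1.2, -0.2)), "sum to 1|non-negative")
  expect_error(complex_population(10, c(0.7, 0.2)), "sum to 1")
})

test_that("seeded generators are bit-reproducible", {
  tr <- membrane_truth(seed = 7)
  expect_identical(simulate_brightness_samples(tr, 500),
                   simulate_brightness_samples(tr, 500))
  expect_identical(simulate_trajectories(0.1, 0.01, 50, 5, seed = 7),
                   simulate_trajectories(0.1, 0.01, 50, 5, seed = 7))
})

test_that("empirical brightness PDF converges to the analytic mixture", {
  # analytic monomer density (closed-form lognormal), not the KDE estimate
  sdlog <- sqrt(log(1 + 0.35^2))
  g <- seq(0, 1500, length.out = 4096)
  rho1 <- brightness_pdf(g, dlnorm(g, log(100) - sdlog^2 / 2, sdlog))
  comps <- nmer_pdfs(rho1, 3)
  tr <- membrane_truth(seed = 24)
  mix_cdf <- function(q) {
    h <- comps[[1]]$grid[2] - comps[[1]]$grid[1]
    d <- 0.55 * comps[[1]]$density + 0.35 * comps[[2]]$density +
      0.10 * comps[[3]]$density
    cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * h))
    stats::approx(comps[[1]]$grid, cdf / max(cdf), xout = q, rule = 2)$y
  }
  ks_dist <- function(n, seed) {
    s <- sort(simulate_brightness_samples(membrane_truth(seed = seed), n)$brightness)
    max(abs(stats::ecdf(s)(s) - mix_cdf(s)))
  }
  d_small <- ks_dist(500, 25)
  d_large <- ks_dist(2e4, 26)
  expect_lt(d_large, 0.02)
  expect_lt(d_large, d_small)
})

test_that("FRAP curve generator honours its closed form", {
  tt <- seq(0, 100, by = 1)
  c1 <- simulate_frap_curve(0.78, 10, tt)
  expect_equal(c1$intensity[length(tt)], 0.78, tolerance = 1e-4)  # plateau
  expect_equal(c1$intensity[1], 0)
  c0 <- simulate_frap_curve(0, 5, tt)
  expect_true(all(c0$intensity == 0))
  c2 <- simulate_frap_curve(1, 10, 10)
  expect_equal(c2$intensity, 1 - exp(-1), tolerance = 1e-12)
  expect_error(simulate_frap_curve(0.5, 10, tt, noise_sd = -0.1),
               "non-negative")
})

test_that("Brownian steps have variance 2 D dt per axis", {
  still <- simulate_trajectories(0, 0.01, 20, 10, seed = 31)
  expect_true(all(still$x == 0) && all(still$y == 0))
  tr <- simulate_trajectories(0.118, 0.01, 100, 100, seed = 32)
  steps <- unlist(lapply(split(tr, tr$track_id),
                         function(d) c(diff(d$x), diff(d$y))))
  v <- mean(steps^2)             # 2e4 pooled per-axis squared steps
  se <- stats::sd(steps^2) / sqrt(length(steps))
  expect_lt(abs(v - 2 * 0.118 * 0.01), 3 * se)
})

test_that("pooled MSD at lag 2 equals 4 D t_lag", {
  tr <- simulate_trajectories(1, 1, 2, 1e4, seed = 33)
  d2 <- do.call(rbind, lapply(split(tr, tr$track_id), function(d) {
    c(dx = d$x[3] - d$x[1], dy = d$y[3] - d$y[1])
  }))
  sq <- d2[, 1]^2 + d2[, 2]^2
  expect_lt(abs(mean(sq) - 8), 3 * stats::sd(sq) / sqrt(length(sq)))
})

test_that("subunit exchange conserves labels and mixes to the binomial limit", {
  pop <- complex_population(4000, c(0.61, 0.39), seed = 41)
  # bleach 50% of fluorophores at random
  set.seed(42)
  pop$fluorescent <- stats::runif(nrow(pop)) < 0.5
  n_fl <- sum(pop$fluorescent)

  expect_identical(apply_subunit_exchange(pop, 0, 1e6), pop)
  expect_error(apply_subunit_exchange(pop, -1, 10), "non-negative")

  mixed <- apply_subunit_exchange(pop, Inf, 300, seed = 43)
  expect_identical(sum(mixed$fluorescent), n_fl)     # conservation
  expect_identical(mixed$size, pop$size)
  f <- mean(pop$fluorescent)
  pred <- enumerate_binomial_composition(c(0.61, 0.39), f)
  obs <- visible_composition(mixed, n_max = 2)
  n_vis <- sum(tapply(mixed$fluorescent, mixed$complex_id, sum) >= 1)
  se <- sqrt(pred[2] * (1 - pred[2]) / n_vis)
  expect_lt(abs(obs[[2]] - pred[2]), 3 * se)
})

test_that("fully labeled populations keep the true composition under exchange", {
  pop <- complex_population(3000, c(0.55, 0.35, 0.10), seed = 44)
  mixed <- apply_subunit_exchange(pop, Inf, 600, seed = 45)
  obs <- visible_composition(mixed, n_max = 3)
  expect_lt(max(abs(as.numeric(obs) - c(0.55, 0.35, 0.10))), 0.03)
  expect_identical(sum(mixed$fluorescent), nrow(pop))
})
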