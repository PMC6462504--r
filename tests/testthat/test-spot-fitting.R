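test_that("count-to-photon conversion is the calibrated linear map", {
  cam <- camera_model(offset = 100, inverse_gain = 2)
  img <- matrix(100, 8, 8)
  expect_true(all(counts_to_photons(img, cam) == 0))
  expect_true(all(counts_to_photons(img + 50, cam) == 100))
  # clipping reported, unclipped mode keeps negatives
  img2 <- matrix(c(90, 110), 4, 4)
  ph <- counts_to_photons(img2, cam)
  expect_equal(attr(ph, "clipped_fraction"), 0.5)
  expect_true(all(ph >= 0))
  ph2 <- counts_to_photons(img2, cam, clip = FALSE)
  expect_equal(mean(ph2), 0)
  # saturated pixels are flagged
  img3 <- matrix(100, 4, 4); img3[2, 2] <- 70000
  expect_length(attr(counts_to_photons(img3, cam), "saturated"), 1)
})

test_that("two rendered monomers 10 pixels apart give exactly 2 candidates", {
  cam <- camera_model()
  em <- data.frame(x = c(3, 3 + 10 * cam$pixel_size), y = c(3, 3),
                   photons = 100)
  ph <- counts_to_photons(render_frame(em, cam, noise = FALSE), cam)
  cand <- detect_spots(ph, detection_threshold = 2)
  expect_identical(nrow(cand), 2L)
  # translation invariance: whole-pixel shift moves detections identically
  em2 <- em; em2$x <- em2$x + 3 * cam$pixel_size; em2$y <- em2$y + 2 * cam$pixel_size
  ph2 <- counts_to_photons(render_frame(em2, cam, noise = FALSE), cam)
  cand2 <- detect_spots(ph2, detection_threshold = 2)
  expect_identical(cand2$row, cand$row + 2L)
  expect_identical(cand2$col, cand$col + 3L)
})

test_that("candidates closer than the separation limit are both discarded", {
  cam <- camera_model()
  em <- data.frame(x = c(3, 3 + 3 * cam$pixel_size, 6), y = c(3, 3, 6),
                   photons = 100)
  ph <- counts_to_photons(render_frame(em, cam, noise = FALSE), cam)
  cand <- detect_spots(ph, detection_threshold = 1, min_separation = 4,
                       smooth_sigma = 0)
  expect_identical(nrow(cand), 1L)  # only the isolated spot survives
})

test_that("blank noise-only frames yield no candidates at the 5-sigma threshold", {
  cam <- camera_model()
  none <- data.frame(x = numeric(0), y = numeric(0), photons = numeric(0))
  n_cand <- vapply(1:20, function(s) {
    ph <- counts_to_photons(render_frame(none, cam, seed = s), cam,
                            clip = FALSE)
    nrow(detect_spots(ph))
  }, integer(1))
  expect_gte(sum(n_cand == 0), 19)
})

test_that("Gaussian fits recover integrated brightness additively for n-mers", {
  cam <- camera_model()
  for (n in 1:4) {
    em <- data.frame(x = rep(5, n), y = rep(5, n), photons = 100)
    ph <- counts_to_photons(render_frame(em, cam, noise = FALSE), cam)
    cand <- detect_spots(ph, detection_threshold = 2)
    sp <- fit_gaussian_spot(ph, cand[1, ], cam)
    expect_identical(sp$status, "ok")
    expect_equal(sp$brightness_B, n * 100, tolerance = 0.01)
    expect_equal(sp$sigma, cam$psf_sigma, tolerance = 0.05)
  }
})

test_that("a candidate on blank background is rejected with a reason code", {
  cam <- camera_model()
  none <- data.frame(x = numeric(0), y = numeric(0), photons = numeric(0))
  ph <- counts_to_photons(render_frame(none, cam, seed = 5), cam, clip = FALSE)
  sp <- fit_gaussian_spot(ph, data.frame(row = 20, col = 20), cam)
  expect_true(sp$status %in% c("low_amplitude", "no_convergence",
                               "sigma_out_of_band"))
  # and an edge candidate cannot be fitted
  expect_identical(fit_gaussian_spot(ph, data.frame(row = 2, col = 20), cam)$status,
                   "edge")
})

test_that("post-bleach control frame of a complete bleach has no spots", {
  tr <- ground_truth(surface_density = 0.8, mobile_fraction = 1, seed = 51)
  stk <- simulate_toccsl_movie(tr, camera = camera_model(field_of_view = c(96, 96)))
  post <- stack_photons(stk, "post-bleach")[[1]]
  inner <- toccslr:::.erode_px(stk$bleach_region, 0.5, stk$camera$pixel_size)
  cand <- detect_spots(post, region = inner,
                       smooth_sigma = stk$camera$psf_sigma / stk$camera$pixel_size)
  expect_identical(nrow(cand), 0L)
})

test_that("surface density is recovered from pre-bleach intensity", {
  cam <- camera_model(field_of_view = c(96L, 96L))
  area <- prod(cam$field_of_view) * cam$pixel_size^2
  render_density <- function(dens, seed) {
    set.seed(seed)
    n <- stats::rpois(1, dens * area)
    em <- data.frame(x = stats::runif(n, 0, 96 * cam$pixel_size),
                     y = stats::runif(n, 0, 96 * cam$pixel_size),
                     photons = toccslr:::rbrightness(n, 100, 0.35))
    counts_to_photons(render_frame(em, cam), cam, clip = FALSE)
  }
  est40 <- estimate_density(render_density(40, 61), cam, 100)
  expect_equal(est40$density, 40, tolerance = 0.10)
  est5 <- estimate_density(render_density(5, 62), cam, 100)
  expect_equal(est5$density, 5, tolerance = 0.15)
  # blank frame -> zero
  blank <- counts_to_photons(
    render_frame(data.frame(x = numeric(0), y = numeric(0),
                            photons = numeric(0)), cam, seed = 63),
    cam, clip = FALSE)
  expect_equal(estimate_density(blank, cam, 100)$density, 0, tolerance = 0.05)
})

test_that("density estimate is linear in the true density", {
  cam <- camera_model(field_of_view = c(64L, 64L))
  L <- 64 * cam$pixel_size
  area <- L^2
  dens <- c(2, 10, 25, 50)
  est <- vapply(seq_along(dens), function(i) {
    set.seed(70 + i)
    n <- stats::rpois(1, dens[i] * area)
    em <- data.frame(x = stats::runif(n, 0, L), y = stats::runif(n, 0, L),
                     photons = toccslr:::rbrightness(n, 100, 0.35))
    ph <- counts_to_photons(render_frame(em, cam), cam, clip = FALSE)
    estimate_density(ph, cam, 100)$density
  }, numeric(1))
  slope <- stats::coef(stats::lm(est ~ dens))[["dens"]]
  expect_equal(slope, 1, tolerance = 0.1)
})
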