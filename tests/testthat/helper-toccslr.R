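# Shared fixtures, built in code. Seeds are fixed so the suite is
# deterministic; the calibration density is reused across files.

# monomer calibration: 5000 single-fluorophore spots, lognormal
# (mean 100 photons, CV 0.35)
calibration_truth <- function() {
  ground_truth(alpha_true = 1, monomer_brightness_mean = 100,
               monomer_brightness_cv = 0.35, seed = 2)
}

calibration_rho1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cal <- simulate_brightness_samples(calibration_truth(), 5000)
      cache <<- estimate_monomer_pdf(cal$brightness)
    }
    cache
  }
})

# plasma-membrane regime: monomers/dimers/trimers 55/35/10
membrane_truth <- function(seed = 1, ...) {
  ground_truth(alpha_true = c(0.55, 0.35, 0.10), seed = seed, ...)
}

# exact visible-spot composition for binomially relabeled complexes:
# enumeration over all fluorophore-label assignments of one complex
enumerate_binomial_composition <- function(alpha_complex, f) {
  n_max <- length(alpha_complex)
  weight <- numeric(n_max)  # P(complex size M, K visible = k) summed
  for (M in seq_len(n_max)) {
    if (alpha_complex[M] == 0) next
    # enumerate all 2^M label assignments explicitly
    for (code in 0:(2^M - 1)) {
      labels <- as.integer(intToBits(code)[1:M])
      k <- sum(labels)
      p <- prod(ifelse(labels == 1, f, 1 - f))
      if (k >= 1) weight[k] <- weight[k] + alpha_complex[M] * p
    }
  }
  weight / sum(weight)
}
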