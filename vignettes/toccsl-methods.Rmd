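---
title: "Single-molecule brightness analysis by TOCCSL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule brightness analysis by TOCCSL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toccslr)
```

## The measurement problem

Fluorescently labeled membrane proteins at typical expression levels
(5–40 molecules/µm²) are far too dense for single-molecule imaging: their
diffraction-limited images overlap. TOCCSL (*Thinning Out Clusters while
Conserving Stoichiometry of Labeling*) solves this by photobleaching a
confined membrane region through a field-stop aperture and imaging the
very onset of the recovery: the first unbleached complexes that diffuse
back into the bleached region appear as isolated, resolvable spots.
Because an intact complex is bleached all-or-none (it is either inside or
outside the aperture), the subunit stoichiometry of the surviving
complexes is conserved — each visible spot's brightness reports how many
active fluorophores it carries.

The protocol per run: a pre-bleach image (surface-density readout), a
50 ms delay, an 800 ms bleach pulse confined to the aperture region, a
post-bleach control image 40 ms later (it must be empty, or the run is
invalid), and the TOCCSL image after a 15–20 s recovery time. These
timings are the defaults of `protocol_timings()`.

## Brightness mixture model

Let $B$ be the integrated brightness (photons) of one diffraction-limited
spot and $\rho_1(B)$ the brightness density of a single fluorophore,
measured by calibration on extensively pre-bleached cells (at most one
active fluorophore per complex). An $N$-mer carrying $N$ independent
active fluorophores has brightness density

$$\rho_N(B) = \underbrace{(\rho_1 * \cdots * \rho_1)}_{N\text{-fold}}(B),$$

and the observed spot-brightness density is the finite mixture

$$\rho(B) = \sum_{N=1}^{N_{\max}} \alpha_N\, \rho_N(B), \qquad
\alpha_N \ge 0,\ \sum_N \alpha_N = 1 .$$

The fractions $\alpha_N$ of visible $N$-mers are the quantity of
interest. Implementation choices:

* **$\rho_1$ estimation** (`estimate_monomer_pdf()`): Gaussian kernel
  density with Silverman's bandwidth on a uniform grid of 2048 points
  from 0 to $N_{\max}$ times the 99.9th sample percentile, so the grid
  holds the $N_{\max}$-fold convolution support. Fewer than 20
  calibration spots is an error; fewer than 200 a warning.
* **Autoconvolution** (`autoconvolve()`): FFT with explicit zero-padding
  (no circular wrap-around), truncated back to the grid; if more than
  $10^{-4}$ of the convolved mass would fall beyond the grid the call
  fails rather than silently renormalizing a clipped density. Mean and
  variance of $\rho_N$ are additive in $N$ to 0.1% / 0.5% — this is
  asserted by the tests for arbitrary calibration input.
* **Fitting criterion** (`fit_mixture()`): maximum likelihood of the spot
  sample under the mixture density, solved by EM over the simplex
  weights. With fixed components the log-likelihood is concave in
  $\alpha$, so EM converges to the global constrained optimum and the
  result is deterministic given the sample and grid. A binned
  non-negative least-squares mode (`method = "ls"`, via
  `pracma::lsqnonneg`) is provided as a cross-check and agrees with ML
  within bootstrap error on simulated data; tests also verify the ML
  solution against exhaustive grid search on small discrete alphabets.
* **Errors** (`bootstrap_alpha()`): 100 random subsamples containing 50%
  of the spots, drawn *without* replacement, refitted; the reported SE is
  the replicate standard deviation divided by $\sqrt 2$ (the half-sample
  estimate of the full-sample SE).
* **Ill-conditioning**: if the calibration CV is below 0.05 the component
  densities are nearly collinear and the fit emits a warning instead of
  failing.
* **$N_{\max}$** defaults to 5. The report layer groups $N \ge 3$ as
  "higher-order" but never forces the displayed monomer + dimer share to
  100%.

`detection_sensitivity()` quantifies what "absent" means: the smallest
injected $\alpha_N$ recovered above twice its bootstrap SE in at least
95% of simulated experiments at a given sample size. A caveat found while
validating it: a handful of very bright spots (e.g. five pentamers in
1000 spots) can legitimately be flagged by the ML fit well above chance,
because high-order components occupy an otherwise empty brightness tail;
reliability at the 95% level still requires far larger fractions.

## Spot detection and photometry

Camera counts are converted to photons as
$(\text{counts} - \text{offset}) \times \text{inverse gain}$
(`counts_to_photons()`). Two numerical details matter in practice and are
deliberate: integrating estimators (surface density) and detection run on
*unclipped* photon images, because clipping read-noise excursions at zero
inflates integrals and skews the noise floor; and detection operates on a
Gaussian-smoothed (matched-filter) copy of the image with a 5·MAD
threshold estimated inside the analysis region, while the photometric fit
uses the raw image. Candidates closer than `min_separation` (default 4 px)
are **both** discarded — an unbiased brightness distribution matters more
than completeness. Each surviving candidate is fitted with a 2-D Gaussian
(Levenberg–Marquardt, `minpack.lm`); the single-spot brightness is
$B = 2\pi A \sigma^2$. Fits are rejected with reason codes when they fail
to converge, the amplitude is not positive, or $\sigma$ leaves the
$[0.7, 1.5] \times$ nominal-PSF band (this removes aggregates,
out-of-focus signal and most unresolved double spots). The surface
density is estimated from the integrated background-corrected pre-bleach
intensity divided by the mean monomer brightness and the area — an
estimator that works where individual molecules are unresolvable — with
spot counting available as a cross-check at low density.

## Mobility

FRAP: the bleached rectangle, eroded by 25% per side ("central part"), is
integrated per frame and normalized to the pre-bleach image; the curve is
fitted with the bounded recovery model
$I/I_0 = m\,(1 - e^{-t/\tau})$, $m \in [0,1]$. The exponent carries a
negative sign: the saturating form is the only one consistent with a
recovery that rises from 0 to a plateau, and the plateau $m$ is the
mobile fraction. Tracking: the time-averaged MSD (overlapping pairs
within tracks, track-averaged with pair-count weights) is fitted as
$\mathrm{MSD} = 4 D t_{\mathrm{lag}} + \text{offset}$ through the first
two lags by default; the offset (localization error) is reported, never
subtracted from $D$.

## Repeat TOCCSL and the exchange model

Running the protocol every 5 minutes on the same cells discriminates two
scenarios. **Stable complexes** are bleached all-or-none, so repeated
runs deplete the number of visible spots but never change the apparent
composition. **Fast subunit exchange** mixes bleached and unbleached
subunits between runs; if the unbleached-fluorophore fraction at run $k$
is $f_k$, labels are binomially distributed over complexes and the
apparent composition among visible spots ($K \ge 1$ active fluorophores)
is

$$\alpha^{\mathrm{app}}_K(f) =
  \frac{\sum_M q_M \binom{M}{K} f^K (1-f)^{M-K}}
       {\sum_M q_M \left[1 - (1-f)^M\right]},$$

with $q_M$ the complex-level size fractions — for a monomer/dimer
population the apparent dimer fraction is
$d f^2 / \left[m f + d\,(2f(1-f) + f^2)\right]$. This is
`exchange_model_predict()`, validated in the tests against exact
enumeration over label assignments. `analyze_repeat_toccsl()` pools spots
per run index, fits $\alpha$ with bootstrap errors, and tests the dimer
fraction for a weighted least-squares trend: $|$slope$| < 1$ SE is
stable, $> 2$ SE exchanging, otherwise inconclusive; a stable verdict
additionally requires the constant-composition model to beat a
two-parameter fast-exchange fit (geometric bleach schedule
$f_k = (1-p)^{k-1}$) after a one-parameter penalty. The depletion trace
and the composition trend are deliberately reported together — depletion
with a flat composition is the signature of stability.

## What the generator emulates — and what it does not

`simulate_toccsl_movie()` renders the full image sequence: complexes with
per-subunit fluorophore labels diffusing by Brownian motion on a torus
(conserving density), a bleach pulse executed in 8 substeps so complexes
crossing the aperture edge during the 800 ms pulse are partially bleached,
an integrated-Gaussian PSF, Poisson shot noise, count offset, inverse
gain and Gaussian read noise. Defaults: 0.16 µm pixels, PSF σ 0.2 µm,
lognormal single-fluorophore brightness with mean 100 photons and CV 0.35
(positive support and right skew, typical of single-GFP TIRF photometry;
the functional form is a declared stand-in — the measurement itself uses
an empirical $\rho_1$, and the estimator accepts any sample). Every
subunit is fluorescent by default (no dark-fluorophore correction, as
none is applied in the analysis either); the immobile fraction (default
22%) is simulated as $D = 0$ molecules that never enter the bleached
region — the protocol is blind to them.

Known deviations from real data, and their consequences:

* No blinking, triplet states or partial photobleaching beyond the
  aperture edge effect; brightness draws are i.i.d. per frame. Passing
  recovery tests therefore demonstrates correctness of the estimators,
  not robustness to photophysics the model excludes.
* `simulate_repeat_toccsl()` is population-level: spatial transport is
  treated as complete mixing between runs (the 5-minute interval far
  exceeds the diffusion time across the region), each run bleaching an
  independent random fraction of the remaining fluorophores. The rendered
  single-run path and the population path are tested against each other
  at the composition level.
* The FRAP stack simulator has a finite reservoir; because global
  equilibration of the bleached hole across the torus is slow, measured
  plateaus sit a few percent below the true mobile fraction. Stack-level
  checks therefore use a ±0.10 tolerance, while the analytic curve
  generator (the path used for headline parameter recovery) is exact.
* At realistic recovery times the rim of the bleached region repopulates
  densest; unresolved close pairs merge into apparent dimers. The
  conservative both-discarded overlap policy and the σ band mitigate but
  do not eliminate this, so rendered-movie composition checks use looser
  tolerances (and fewer spots) than the draw-based ones. This mirrors the
  real experiment's resolvable-density precondition (≲1 spot/µm², warned
  about in the stack metadata).

## Problem sizes and reproducibility

All stochastic entry points take explicit seeds and are bit-reproducible;
pipeline reports are byte-identical across reruns with the same inputs.
The standard problem sizes used throughout the package's own analyses:
10,000 mixture spots with a 5,000-spot calibration; 11 FRAP cells; 300
tracks of 100 steps (≥10⁴ pooled displacements, giving SE(D) ≈ 0.002
µm²/s at D = 0.118); 37 cells × 10 runs for repeat TOCCSL; bootstrap
with 100 replicates (40–60 where it is merely an internal weight). These
sizes reproduce the targeted regime comfortably; scaling any of them up
is a matter of the corresponding argument.

The `analysis/` directory contains the four numbered drivers
(`01_mobility.R` … `04_repeat_toccsl.R`) that run these analyses
end-to-end and write their tables under `results/`; they, together with
the exported functions, are the package's interface.
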