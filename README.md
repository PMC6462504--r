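# toccslr

Single-molecule brightness analysis of membrane-protein oligomerization
with the TOCCSL photobleaching protocol, as an R package plus a set of
numbered analysis drivers.

## The problem

Membrane transporters such as the dopamine transporter are suspected to
work as dimers or higher oligomers, but at native surface densities
(5–40 labeled molecules/µm²) their fluorescence images overlap and
single molecules cannot be resolved. TOCCSL (*Thinning Out Clusters
while Conserving Stoichiometry of Labeling*) photobleaches a confined
membrane region through a field stop and images the first unbleached
complexes diffusing back in — isolated, diffraction-limited spots whose
integrated brightness *B* reports the number of active fluorophores they
carry.

With a calibrated single-fluorophore brightness density ρ₁(B), the
density of an N-mer is the N-fold autoconvolution ρ_N(B), and the
observed spot-brightness density is fitted as the constrained mixture

    ρ(B) = Σ_N α_N ρ_N(B),   α_N ≥ 0,  Σ α_N = 1,

whose weights α_N are the oligomer fractions. Errors come from 100
bootstrap refits of 50%-subsamples (SD/√2). The package implements the
full chain — photon conversion, matched-filter spot detection, 2-D
Gaussian photometry, surface-density estimation, autoconvolution,
constrained maximum-likelihood deconvolution (EM on the simplex, with a
binned non-negative least-squares cross-check), FRAP mobile-fraction and
MSD diffusion fitting (MSD = 4·D·t_lag + offset), and a repeat-TOCCSL
stability analysis that discriminates stable complexes (constant
composition, depleting spot counts) from fast subunit exchange (binomial
label mixing shifting the apparent distribution toward monomers) — plus
a synthetic-data generator that emulates the whole protocol with known
ground truth, so every estimator is verified by parameter recovery.

## Worked example

Calibrate the monomer density, simulate a recovery-frame sample in the
monomer/dimer/trimer 55/35/10 regime, and deconvolve it:

```r
library(toccslr)

cal  <- simulate_brightness_samples(ground_truth(alpha_true = 1, seed = 2), 5000)
rho1 <- estimate_monomer_pdf(cal$brightness)

truth <- ground_truth(alpha_true = c(0.55, 0.35, 0.10), seed = 1)
spots <- simulate_brightness_samples(truth, 10000)
fit   <- fit_mixture_boot(spots, rho1, n_max = 5, n_reps = 100, seed = 3)
fit
#> <mixture_result> ml fit of 10000 spots, N_max = 5
#>   alpha_1 = 0.553 +/- 0.005
#>   alpha_2 = 0.345 +/- 0.006
#>   alpha_3 = 0.102 +/- 0.003
#>   alpha_4 = 0.000 +/- 0.000
#>   alpha_5 = 0.000 +/- 0.000
#>   residual L2 = 0.003819
```

The fit recovers the generating fractions within one bootstrap SE:
55.3% monomers, 34.5% dimers, 10.2% trimers, and no spurious
higher-order component. `plot_mixture(spots, fit)` draws the standard
PDF-decomposition figure (observed density, fitted mixture, weighted
n-mer contributions).

The numbered drivers under `analysis/` run the complete analyses and
write their tables to `results/`:

| driver | what it does |
|---|---|
| `analysis/01_mobility.R` | FRAP mobile fraction on an 11-cell ensemble (77.9 ± 0.8% at truth 78%) and MSD diffusion fit (D = 0.1179 ± 0.0018 µm²/s at truth 0.118) |
| `analysis/02_brightness_mixture.R` | calibration → autoconvolution → mixture fit with bootstrap errors, plus the decomposition figure |
| `analysis/03_density_groups.R` | oligomer distribution at ~5 vs ~40 molecules/µm² (density estimates read back from rendered pre-bleach images; Δα₂ = 0.6 combined SE → no density dependence) |
| `analysis/04_repeat_toccsl.R` | 10-run repeat TOCCSL on 37 simulated cells: stable → verdict *stable*, slope 0.0003 ± 0.0008 per run while spots deplete 9352 → 1787; fast exchange → verdict *exchanging*, α₂ 0.36 → 0.07 |

## Layout

```
R/                  implementation (generator, spot fitting, mixture,
                    mobility, protocol pipeline)
analysis/           numbered end-to-end drivers (write to results/)
scripts/acceptance.R
tests/testthat/     unit, property and parameter-recovery suites
vignettes/toccsl-methods.Rmd   models, assumptions, design choices
```
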