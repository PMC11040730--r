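# nmrdecon

Bayesian deconvolution of ¹H NMR spectra of multi-compound reaction
mixtures.

Crude reaction mixtures — the unpurified product of a borylation, an
olefination, a partial oxidation — give a single ¹H NMR spectrum in which
the resonances of every product, isomer and leftover starting material
overlap. `nmrdecon` answers two questions from that one spectrum, given
only *predicted* spectra for a list of candidate compounds: **which
candidates are actually present**, and **in what relative concentrations**.
Because the method tolerates substantial error in the predicted chemical
shifts, the candidate spectra can come from cheap predictions (DFT
shieldings passed through a linear calibration, or even rule-based
estimates) instead of measured reference spectra.

## The model

Each candidate compound is a set of resonances: an isotropic shift
δ (ppm), a proton-count weight a, first-order J-couplings (N equivalent
partners split a line into N+1 lines with binomial intensities, adjacent
lines J Hz apart), and a Lorentzian natural linewidth (fwhm 2 Hz by
default, encoding the time-domain decay λ = π·fwhm). Both the observed
spectrum and the simulated candidates are broadened with a 10 Hz Gaussian
apodization and normalized to unit area, so the fit compares probability
densities.

The joint posterior is sampled by gradient-based (Hamiltonian) MCMC over

- one mixture weight per candidate, w_i ~ Half-Cauchy(1),
- one shift offset per resonance, Δ_r ~ Normal(0, σ_method²) where
  σ_method ≈ 0.4 / 0.1 / 0.01 ppm for rule-based / DFT / library-derived
  shifts,
- a residual noise scale σ ~ Half-Cauchy,

with the observed density modeled as the normalized weighted sum of
candidate lineshapes plus i.i.d. Gaussian noise. Concentrations are
summarized on the unit simplex by the geometric-mean center ξ of the
closed weight draws; candidates whose center falls below a cutoff
(default 5%) are pruned and the fit repeats until the surviving set is
stable. Optionally the spectrum is first segmented into merged ±0.5 ppm
intervals around the predicted lines, ranked by Bernoulli information
entropy H(p) of the fraction p of candidates appearing in each interval,
and fit sequentially — high-entropy regions eliminate candidates early.

DFT shieldings are converted to shifts with the built-in calibration line
δ = −0.9548·σ_iso + 30.435 ppm (R² = 0.9941); refit your own with
`fit_calibration()`.

## Worked example

Deconvolute the shipped synthetic mixture (three candidates in a
0.55 / 0.30 / 0.15 ratio) against its candidate library:

```r
library(nmrdecon)

obs <- read_spectrum(system.file("extdata", "synthetic_mixture.csv",
                                 package = "nmrdecon"))
lib <- read_library(system.file("extdata", "synthetic_library.json",
                                package = "nmrdecon"))

fit <- deconvolute(obs, lib, cutoff = 0.05,
                   warmup = 500, samples = 1000, seed = 1)
tidy(fit)
```

```
# A tibble: 3 × 5
  compound estimate conf.low conf.high present
  <chr>       <dbl>    <dbl>     <dbl> <lgl>
1 olefin_E    0.526    0.523     0.529 TRUE
2 olefin_Z    0.308    0.306     0.309 TRUE
3 aldehyde    0.166    0.164     0.169 TRUE
```

`estimate` is the geometric-mean center of the posterior mole fractions —
recovering the true 55/30/15 composition to within about two points of
mole fraction under the library's stated 0.1 ppm shift uncertainty — and
`present` is the cutoff call. `autoplot(fit)` overlays the observed and fitted densities;
`plot_composition(fit)` draws the composition with credible intervals;
`glance(fit)` reports sampler diagnostics. The same operations are
available from the shell via `exec/nmrdecon deconvolute --spectrum
obs.csv --library lib.json --report out.json`.

Synthetic benchmarks (generate candidates, mix with Dirichlet weights,
jitter shifts by the prediction error, deconvolute, score) run via:

```r
b <- run_benchmark(n_true = 5, n_candidates = 10, theory_sigma = 0.1,
                   n_repeats = 10, seed = 1, warmup = 500, samples = 1000)
attr(b, "summary")
```

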