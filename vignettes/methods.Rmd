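---
title: "Methods: Bayesian deconvolution of mixture NMR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian deconvolution of mixture NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdecon)
```

This vignette is the package's own account of its model, its numerical
choices, and the places where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

A crude reaction mixture gives one ¹H NMR spectrum in which several
compounds overlap. Given *predicted* spectra for a library of candidate
compounds — resonance shifts (possibly from DFT shieldings through a
linear calibration), proton weights, J-couplings, and a stated shift
uncertainty per prediction method — the package decides which candidates
are present and estimates their relative concentrations. The central
difficulty is that predicted shifts are wrong by 0.01–0.4 ppm depending
on their source, so the fit must treat the shifts themselves as unknowns.

## Forward model

A resonance is modeled as an exponentially decaying time-domain signal,
whose real spectrum is a unit-area Lorentzian of full width at half
maximum `fwhm_hz` (default 2 Hz; the decay rate is λ = π·fwhm). First-
order J-coupling to N equivalent spins splits a line into N + 1 lines
with intensities from row N of Pascal's triangle and adjacent-line
spacing J; several coupling groups convolve. `expand_multiplet()` is
verified in the tests against brute-force enumeration of all 2^N spin
states.

One reading note on splitting geometry: a doublet is centered on the
parent shift with lines at ±J/2, i.e. the *offset of each line* is J/2
while the *spacing between lines* is J. Descriptions that quote "spacing
J/2" are interpreted as the half-offset; standard first-order multiplet
geometry (spacing J) is what the code implements.

Spectra are sampled on a uniform ppm grid (default 0–10 ppm, 2¹⁴
points); Hz convert to ppm through the spectrometer frequency (default
500 MHz). Rendering warns when the grid gives fewer than four points per
linewidth.

Before fitting, both the observed spectrum and the candidates receive a
Gaussian apodization of 10 Hz fwhm. This deliberately discards multiplet
fine structure: after broadening, J-couplings barely affect the
lineshape, which justifies holding them fixed during fitting, and the
smooth profiles give the sampler useful gradients even when predicted
and observed peaks are misaligned. Both sides are then normalized to
unit trapezoid area — the fit compares probability densities, which
removes the arbitrary intensity scale of an NMR acquisition (an
invariance the tests check directly).

## Posterior and sampler

Latent variables:

* one weight per candidate, `w_i ~ Half-Cauchy(scale = 1)`, sampled on
  the log scale. Only ratios of weights matter after normalization; the
  heavy-tailed prior is weakly informative on the relevant range and its
  scale is deliberately uncritical.
* one shift offset per resonance, `Δ_r ~ Normal(0, shift_sigma²)`, with
  `shift_sigma` the library's stated prediction error: 0.4 ppm
  (rule-based), 0.1 ppm (DFT), 0.01 ppm (literature shifts). An optional
  soft wall approximates truncation at ±4 prior sd
  (`truncate_shifts = TRUE`) for spectra where lines must not wander
  between crowded regions.
* a residual scale `σ ~ Half-Cauchy(scale = 0.5)`, with the observed
  density modeled as the normalized model curve plus i.i.d. Gaussian
  noise at every grid point. The likelihood form is a modeling choice
  (nothing about real baselines is exactly i.i.d. Gaussian); the
  self-tuning σ absorbs both noise and lineshape mismatch.

The sampler is an adaptive Hamiltonian Monte Carlo written for this
posterior (Rcpp, analytic gradients — checked against finite differences
in the tests): dual-averaging step-size adaptation toward 0.8
acceptance, Stan-style expanding windows that re-estimate a diagonal
mass matrix during warmup, and trajectory lengths jittered uniformly up
to `l_max` (default 15) leapfrog steps. Jittered fixed-length
trajectories replace full No-U-Turn tree building; they are in the same
gradient-based class and considerably simpler, at the cost of a tuning
constant. Defaults are 1000 warmup and 3000 kept iterations; the
benchmarks use 500/1000, which the self-fit tests show is sufficient for
these problem sizes.

Two details matter for this posterior's geometry:

* **Annealing by initialization.** Well-fit shift posteriors contract to
  ~10⁻⁴ ppm, ~500× narrower than their priors; a chain initialized with
  a small noise scale freezes immediately. σ is therefore initialized at
  the standard deviation of the observed density, so the early warmup
  runs against a deliberately weak likelihood and tightens as the fit
  improves, while the expanding windows re-learn the coordinate scales
  as they shrink.
* **Truncated evaluation.** Inside the sampler each line is a
  Thompson–Cox–Hastings pseudo-Voigt (its Lorentzian natural width
  convolved with the Gaussian apodization), evaluated on a window of
  `0.3 + 3·shift_sigma` ppm (capped at 2 ppm) around the line. The
  Gaussian component is only evaluated where it exceeds ~10⁻¹⁶ of its
  peak. The truncated Lorentzian tails cost well under 1% of line area;
  the pseudo-Voigt differs from the exact Fourier convolution by a
  similar margin. Both errors are diffuse and absorbed by σ.

## Summaries on the simplex

Relative concentrations live on the unit simplex, so posterior weight
draws are closed (divided by their sum) and summarized by the
geometric-mean center ξ — the compositional analogue of the mean — not
the arithmetic posterior mean. Zeros are floored at 10⁻¹² before logs.
Recovery error is the mole-fraction MAE, `(100/D)·Σ|x̂_i − x_i|`, with D
the full candidate count including absent candidates; present/absent
calls are scored by `(TP+TN)/(TP+TN+FP+FN)`.

## Pruning loop and segmentation

`deconvolute()` fits, removes candidates whose center falls below the
cutoff (default 5%; 10% is more robust for noisy spectra with impurity
peaks), and refits until the surviving set repeats. If at stability any
surviving resonance still has a shift posterior spread above twice its
prior sd — the signature of a peak lying outside its nominal prior range
— one extra iteration runs with all shift priors widened to three times
the base sd (0.3 ppm at the DFT level).

With `intervals = TRUE`, merged ±0.5 ppm windows around the predicted
lines are fit sequentially before the global fit, ordered by the
Bernoulli information entropy of p = (members)/(library size); ties go
to the least-shielded interval first, as when reading a spectrum by
hand. The entropy is read over the present/absent indicator rather than
as categorical entropy over member identities, because p is defined as a
fraction of the library, and intervals with p near ½ are precisely the
ones most likely to eliminate candidates. Interval fits use an
absolute-scale likelihood (no per-interval normalization): closure over
an interval's members alone could never express "this region is empty",
which is the very case — e.g. an aldehyde/acid region with no observed
signal — where interval fitting eliminates candidates fastest. The
pruning statistic there is the geometric mean of (coefficient ×
full-spectrum area), a member's share of the total observed signal.
Weights remain global; only the grid and the candidate lines are
restricted.

## The synthetic benchmark generator

`gen_component()` draws what the recovery study treats as ground truth:
10 resonances per compound, shifts uniform on 0–10 ppm, integer proton
weights 0–3, exactly 5 resonances carrying one coupling of 5 or 10 Hz
(each an independent doublet — coupling partners are not paired), 2 Hz
natural width. Mixture weights come from a flat Dirichlet over the true
components; the composite is scaled to unit maximum; optional baseline
noise adds i.i.d. Gaussian deviations of sd 0.01 (about 1% of the
highest peak) per grid point, negative values kept. The candidate
library handed to the fit is the truth with every shift independently
jittered by `Normal(0, theory_sigma²)` — this jitter is the *entire*
difference between prediction methods in the benchmark.

Two scoring conventions deserve explanation:

* **MAE divisor.** MAE averages over all candidates, counting absent
  ones at zero. Alternatives (divide by true components only) change the
  numbers by a constant factor and are not used.
* **Truth labeling at the cutoff.** A flat Dirichlet over five
  components puts a component below 5% in roughly one run in five. The
  cutoff that declares a *prediction* absent is therefore also applied
  to the *truth* when scoring classification: a component mixed in at
  3% is labeled absent on both sides. Without this, even a perfect
  estimator's expected accuracy in the 10-candidate benchmark is capped
  near 91% by sub-cutoff true components alone, and the library-quality
  accuracy level reported for this style of benchmark could not be
  reached by any method. With it, classification errors measure what
  they should: disagreement about components that matter at the cutoff
  scale.

What the generator deliberately does not emulate: correlated shifts
between structurally similar candidates (real constitutional isomers
have *similar* spectra; synthetic components are independent, which
makes the synthetic task easier at large shift error), second-order
multiplets, phase and baseline distortions, solvent and impurity peaks,
and reciprocal coupling-partner bookkeeping. Passing benchmarks
therefore demonstrate correct inference under the stated error model,
not performance parity on arbitrary experimental spectra.

## Problem sizes

The test suite runs unit fits with small libraries (2–6 compounds, 1024
fitting points, warmup 100–400) and the acceptance checks at a scaled
benchmark design: 10 repeats per configuration, warmup 500 / samples
1000 per fit, composites rendered on 2¹⁴ points over −1.5…11.5 ppm and
fit on 2560 points. `scripts/acceptance.R` keeps the full 15 repeats and
1000-iteration warmup but 1000 kept draws per fit: at 0.4 ppm shift
error the posterior is hard enough that warmup length visibly affects
recovery, while the number of kept draws past 1000 does not. The
full-scale defaults (15 repeats, warmup 1000 / samples 3000) are one
flag away in `run_benchmark()`.

## Known limitations

* Strong (second-order) coupling is out of scope; multiplets are
  first-order.
* J-couplings and linewidths are held fixed; only shifts and weights are
  sampled.
* Concentrations are relative; no absolute (molar) quantification.
* A single chain is run per fit; at 0.4 ppm shift error the posterior is
  visibly multimodal and individual fits can report divergences — the
  benchmark averages remain informative, single fits at that error level
  should be treated cautiously.
* The interval-mode pruning statistic (signal share) is a proxy for
  concentration share; the final composition always comes from the
  closing global fit.
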