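---
title: "Methods: viscoelastic creep fitting, GPC calibration and morphometry in wallcreep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viscoelastic creep fitting, GPC calibration and morphometry in wallcreep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallcreep)
```

## Scope

`wallcreep` implements the quantitative backbone of a plant cell-wall
biomechanics study: (i) fitting a four-element Kelvin–Voigt–Burgers
viscoelastic model to creep-extension curves of stem segments, (ii)
estimating xyloglucan molecular mass from gel-permeation chromatography
(GPC) elution profiles calibrated with dextran size markers, (iii) linear
standard-curve quantification of sugars and xyloglucan oligosaccharides,
and (iv) carpel/exocarp morphometry with two-group comparisons. Because
raw instrument traces of this kind are rarely published, the package ships
a synthetic-data generator with known ground truth; every estimator is
validated by parameter-recovery round trips against it.

## The creep model

A stem segment held between two clamps under a constant per-area load
$P_0$ deforms as

$$\varepsilon(t) = \frac{P_0}{E_0}
  + \sum_{n=1}^{3} \frac{P_0}{E_n}\left(1 - e^{-t/\tau_n}\right),$$

an instantaneous spring $E_0$ in series with three Kelvin–Voigt elements
(spring $E_n$ in parallel with a dashpot), each with retardation (delay)
time $\tau_n$. The dashpot viscosities are derived, not fitted:
$\eta_n = E_n \tau_n$. The model assumes load is applied as a step at
$t = 0$ (the clamp ramp, driven at 0.5 mm/s, is not modelled) and contains
no unbounded-flow term, so deformation saturates at
$P_0 \sum_n 1/E_n$ (including $n = 0$). Deformation is stored as raw
extension unless the protocol carries a gauge length, in which case it is
strain; the fit is invariant to this choice up to a rescaling of the
moduli. Stress stays in gram-force per mm² throughout, the unit in which
such creep meters report; `GF_PER_MM2_IN_PA` converts to SI.

The default protocol is the one the instrument emulates: $P_0 = 25$
gf/mm², samples every 0.5 s for 600 s (1201 points).

### Parameter estimation

`fit_burgers()` minimizes the unweighted sum of squared deviations over
the seven parameters with Levenberg–Marquardt (`minpack.lm::nls.lm`),
using analytic derivatives. Numerical choices that matter:

- **Log-parameter space.** All seven parameters are strictly positive;
  optimizing their logarithms enforces this without penalties and makes
  restart jitter naturally multiplicative.
- **Box constraints.** Retardation times are confined to
  $[\mathrm{d}t/2,\ 10\,T]$ — below half a sampling interval an element is
  indistinguishable from the instantaneous spring, beyond ten durations
  from the asymptote. Moduli get generous data-scaled bounds.
- **Multi-start.** Three-exponential fits are multi-modal, so the solver
  restarts (default 16 times) from the heuristic initial guess perturbed
  by log-normal jitter (SD 0.5 on the log scale). Lowest SSE wins; ties
  (relative SSE difference below $10^{-12}$) break toward the smaller
  log-parameter norm. A fixed `seed` in `fit_config()` makes the whole
  procedure bit-reproducible.
- **Initial guess.** $E_0 = P_0/\varepsilon(t_1)$; the retarded compliance
  observed between the first and last sample is split equally over the
  three elements; $\tau$ starts log-spaced across $[2\,\mathrm{d}t, T]$.
- **Identifiability flags.** Results are returned, never suppressed, but
  flagged when two fitted $\tau$ lie within a factor of two of each other
  (elements merged), when $\tau_3$ exceeds the record length (asymptote
  unobserved), or when the curve is essentially flat (Kelvin terms
  unidentifiable; $E_0$ is still well determined as $P_0/c$).
- **Canonical order.** $\tau_1 \le \tau_2 \le \tau_3$ is imposed at
  construction, breaking the permutation symmetry of the elements.

Weighted least squares is available through the `weights` argument; the
default is unweighted because no noise model for the instrument is
established. The `fixed` argument pins any subset of parameters, which is
how the test suite reduces the model to one element and checks the solver
against an exhaustive lattice search.

## GPC molecular-mass estimation

Size-exclusion physics dictates that log molecular mass falls linearly
with elution time over a column's working range, and that larger
molecules elute first; `marker_set()` rejects marker tables violating
this. `fit_mw_calibration()` fits $\log_{10}(\mathrm{MW}) = a + b\,r$ by
ordinary least squares to the dextran markers (150, 500, 2500 kDa); with
collinear markers the line interpolates them exactly. Point-to-point
interpolation is a conceivable alternative; log-linear OLS is the
documented default as it is the standard practice and the only choice
that extrapolates sensibly.

`peak_molecular_mass()` reports the mass of the fraction with maximal
xyloglucan content — the peak-fraction estimator, matching how such
results are reported — with ties resolved toward the earlier-eluting
(larger) fraction. Its resolution is therefore one fraction width: with
30 s fractions at 1 ml/min and the default retention law, about 0.05
decades of mass. `mass_distribution()` provides the full per-fraction
mass assignment, contents normalized to sum to one, and a content-weighted
log-scale centroid as a clearly separate alternative estimator.
Assignments outside the marker range are returned but flagged as
extrapolation.

## Standard-curve quantification

One generic linear calibration covers the three applications (glucose for
phenol–sulfuric total sugar, tamarind xyloglucan for iodine staining,
XXXG for HPAEC-PAD): OLS of response on amount, intercept fitted by
default with a `through_origin` flag, inverse quantification
$(y - b)/a$. Negative recovered amounts are returned and flagged rather
than clipped, and flags mark extrapolation below/above the standard range
and results under a user-supplied limit of detection (precedence:
negative > extrapolated > below-LOD). No LOD value is asserted by the
package; trace-level reporting conventions differ between instruments.
Inversion refuses slopes that are zero relative to the response scale.

## Morphometry

Mean exocarp cell width is carpel semicircle circumference divided by the
cell count along it. When per-replicate vectors are supplied the width is
computed per replicate and then averaged — the reconstruction consistent
with published tables, where the width row is not exactly the ratio of
the circumference and count means — with the ratio form used only for a
single pooled pair. `two_sample_t()` computes Student's pooled
two-sample t (the table convention for balanced designs) from summary
statistics, with Welch available by flag; both are verified against
`t.test()` on raw vectors. Degenerate zero-variance groups with equal
means return $t = 0, p = 1$ by convention. Whether SDs in such tables are
taken across sections or plants is ambiguous in general; the functions
accept either labelling and do not guess.

## The synthetic-data generator

The generators emulate the instruments at the level of their exported
summaries, with additive homoscedastic Gaussian noise everywhere (no
instrument noise model being available, SDs are explicit arguments, with
0 — the exact forward model — as the visible default):

- `simulate_creep()`: the forward Burgers model sampled on the default
  protocol grid (1201 points), plus optional noise.
- `simulate_gpc()`: marker positions placed exactly on a ground-truth
  log-linear retention law (default `elution = 60 − 10·log10(MW kDa)` min,
  chosen so the three dextrans elute in a realistic 26–38 min window on a
  60 cm column at 1 ml/min), and an analyte profile Gaussian in
  $\log_{10}(\mathrm{MW})$ (default SD 0.15 decades, a realistic
  polysaccharide polydispersity) sampled at 30 s fraction midpoints over
  20–45 min and normalized to a 700 µg load. Genotype presets pin the
  peak at 660 (Ws), 540 (Ler), 240 (trg1-1) and 200 (trg1-2) kDa.
- `simulate_standards()` / `simulate_morphometry()`: linear responses
  with response noise; Gaussian group draws from the bundled morphometry
  presets (fruit length 12.2 ± 0.6 vs 8.3 ± 0.5 mm with n = 20,
  circumference and cell count with n = 4).

Every generator requires a seed and is bit-deterministic given it, and
each emits exactly the CSV dialect its reader accepts, so
generate → write → read round-trips are lossless.

What the generators do **not** emulate — and hence what passing recovery
tests do not show about real data: drift and heteroscedastic detector
noise, the clamp loading ramp, band broadening and column non-ideality in
GPC, non-Gaussian biological variation, and any correlation between
traits within a replicate. Recovery results on synthetic data bound the
estimator error under the stated noise model only.

## Validation problem sizes

The recovery studies run at the sizes the package's own tests use:
noiseless creep round trips on single 1201-point curves (relative error
below $10^{-3}$, in practice machine precision); a 100-replicate
Monte-Carlo at 0.5 % additive noise for the median-$E_0$-error bound
(2 %); 20 replicates for the residual-SD consistency property; lattice
searches of about 7 500 nodes for the one-element oracle comparison.

## Known limitations

- The printed creep equation omits a pure-viscous flow term
  ($P_0 t/\eta_0$); the package implements the bounded model exactly, so
  tissues with genuine unbounded flow will show structured residuals at
  long times.
- With fewer than ~3 decades of well-separated retardation times inside
  the sampling window, the three-element fit is weakly identified; the
  flags report this but cannot repair it.
- The peak-fraction mass estimator is quantized to the fraction grid;
  use the centroid output when sub-fraction resolution matters.
- Per-area stress units (gf/mm²) follow the instrument convention; mixing
  with SI-calibrated data requires explicit conversion.
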