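---
title: "Normative quantitative EEG: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative quantitative EEG: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnorm)
```

This vignette is the package's account of the science it implements: the
spectral and normative models, the estimators chosen where several were
defensible, the numerical conventions, and what the synthetic-data tests
do and do not demonstrate about real recordings.

## The narrow-band spectral model

The unit of analysis is a set of artifact-free epochs selected by an
expert — the package deliberately contains no artifact detection. Each
epoch of `N` samples at rate `fs` is mean-corrected per channel
(reference and offset artifacts carry no quantitative meaning),
optionally Hann-tapered, and transformed by the FFT. The cross-spectral
matrix at bin `k` is the epoch average (Bartlett estimator, no overlap)

$$S_k = \frac{2}{N^2 U E} \sum_{e=1}^{E} \overline{V_e(\cdot,k)}\, V_e(\cdot,k)^{\mathsf T},$$

with `U` the mean squared taper weight (1 with no taper). The
normalization is chosen so that, untapered, the one-sided diagonal
spectrum sums over the full grid to the epoch-mean channel variance —
Parseval holds exactly, which the tests verify to machine precision. The
default is *no* taper: epochs are short, hand-selected windows, and the
untapered estimator keeps the power bookkeeping exact; Hann is available
for users who prefer lower leakage at the cost of effective resolution.

The analysis grid excludes DC and runs in steps of `fs/N` strictly below
`fmax` (default 19.5 Hz). One boundary nuance: when `fmax` lands exactly
on a bin — as when requesting the full one-sided grid up to the Nyquist
frequency — that bin is retained (un-doubled), because power conservation
requires it. For the classical geometry, 2.56-s epochs sampled every
5 ms, the resolution is 0.390625 Hz; bin labels are conventionally
printed on the rounded spacing, so bin `k` is displayed as
`k × 0.39` Hz and the default 49-bin grid reads 0.39–19.11 Hz while the
exact frequencies (up to 19.140625 Hz) are kept internally. Both the
exact values and the display convention are tested.

Coherence is reported in the magnitude-squared convention,
$|S_{ij}|^2/(S_{ii}S_{jj})$ — both common conventions live in [0, 1], and
the choice is recorded in the output metadata. The phase convention is
$S_{ij} = \overline{V_i} V_j$, so a channel lagging behind channel `i`
shows a negative phase difference. Two degenerate cases are documented
rather than raised: a single epoch makes every coherence identically 1
(rank-one cross-spectrum), and a zero-power channel flags its pairs as
undefined.

## The broad-band model

Absolute Power, Relative Power and Mean Frequency are band aggregates of
the raw (never log) narrow-band spectrum. Band assignment is half-open
`[low, high)` on the displayed bin labels so no bin is double-counted;
the default edges place, on the 0.39 Hz grid, Delta on bins 4–9
(1.56–3.51 Hz labels), Theta on 10–19, Alpha on 20–32 and Beta on 33–49,
with Total their union. Edges are configurable and written into every
output header. RP is a partition of unity over the four bands by
construction; MF is the power-weighted mean frequency and falls back,
flagged, to the band midpoint when a band is empty of power.

## Global Scale Factor

Recording gain (amplifier calibration, electrode impedance) multiplies
all spectral power by a subject-specific constant that has nothing to do
with neurophysiology. On the log₁₀ scale this is an additive offset, and
the package estimates it as the grand mean of `y − μ(age)` over all scalp
channels and bins — the maximum-likelihood estimate under i.i.d. Gaussian
log-residuals, and the unique value that zeroes the grand-mean residual
after correction. Two consequences are tested end to end: rescaling the
raw EEG amplitude by `c` moves the estimate by exactly `2 log₁₀ c`, and
z-maps computed with GSF correction are invariant (≤ 1e−9) to such
rescaling. The factor is estimated at scalp level only and the same
offset is applied to source log spectra: a single sensor gain propagates
linearly through the (linear) inverse. Estimation uses the full
frequency grid; no sub-band restriction is applied. When norms are fitted
from a cohort the chicken-and-egg problem (no norms yet to estimate GSF
against) is resolved by one fixed iteration: fit preliminary norms
without GSF, estimate each subject's factor against them, refit once.

## Spherical head model and ridge inverse

Without individual anatomy, the forward model is the analytic potential
of a current dipole in a homogeneous conducting unit sphere with
insulating exterior, evaluated by its Legendre-series solution

$$V = \frac{1}{4\pi\sigma}\sum_{n\ge 1}\frac{2n+1}{n}\,f^{\,n-1}
\Big[n\,q_r P_n(\cos\gamma) + q_t \cos\phi\, P_n^1(\cos\gamma)\Big],$$

truncated once `f^(n-1) < 1e-12` (`f` the source eccentricity, ≤ 0.85
here, so at most ~170 terms). The tests validate the series three
independent ways: the central-dipole closed form, the closed-form
infinite-medium dipole against the expansion's singular part, and a
finite-difference check that the radial current vanishes at the scalp.
Source voxels sit on a regular Cartesian grid (spacing 0.85/4 by
default, ~257 voxels) inside the ball of radius 0.85; columns are
average-referenced, conductivity defaults to 0.33 S/m, and orientation is
free (three moment columns per voxel) or radial.

The inverse is the ridge (minimum-norm) operator
`T = Kᵀ(KKᵀ + λI)⁻¹`, computed by Cholesky factorization, with lead-field
voxel blocks rescaled to unit Frobenius norm first (depth-bias
mitigation; toggleable). λ is selected by generalized cross-validation on
the stacked real/imaginary per-epoch Fourier coefficients over all bins —
one global λ, cheaper and stabler at desk scale than per-bin selection;
the GCV curve is returned for inspection. GCV is scale-equivariant, so
the λ *choice* does not disturb the GSF invariance above.

Source power is the diagonal of `T S_k Tᴴ`, never materializing the
voxel-by-voxel matrix, summed over each voxel's moment components.  Two
output conventions are provided, and the distinction matters:

* `standardize = "none"` (default) undoes the depth rescaling and reports
  physical (dipole moment)² per bin — the right scale for normative
  modeling of source spectra.
* `standardize = "resolution"` divides each voxel's power by its diagonal
  resolution-matrix block (`j_v' R_{vv}^{-1} j_v`) — a dimensionless
  standardized activity index. During development we measured that the
  physical-units map, argmax-ed over voxels, localizes a simulated
  20 dB-SNR dipole to within one grid neighbor in well under half of the
  runs: undoing the depth weights amplifies reconstruction noise at
  low-gain voxels far from every electrode (the bottom of the sphere),
  which then capture the maximum. The standardized index has the
  classical exact-localization property for a noiseless single dipole and
  achieved 50/50 correct localizations in the same benchmark, so it is
  the estimator the localization tests and any "where is the source?"
  question should use.

Full variable-resolution penalties (anatomical weights, spatial
Laplacians) and realistic BEM/FEM head models are out of scope; the ridge
variant over a spherical model is the implemented method.

## Normative age regression

For every location and bin the transformed spectrum `y = log₁₀(power +
1e−12)` is regressed on a polynomial in `u = log₁₀(age)`; one QR
factorization of the shared design serves all 931 (scalp) or ~12,000
(source) responses at once. The heteroscedastic SD is fitted by
regressing `|r|·√(π/2)` on the same basis — for Gaussian residuals the
conditional mean of `|r|` is `σ√(2/π)`, so the half-normal multiplier
makes the fit consistent for `σ(age)` — and evaluation floors the result
at `σ_floor = 0.01` log₁₀-units so z-scores never divide by ~0. A
log-domain SD regression was considered and rejected after measurement:
its multiplicative noise at realistic cohort sizes (n ≈ 211) inflated the
pooled SD of fresh in-model z-scores to ~1.12–1.23, outside any
reasonable calibration band, while the linear half-normal fit yields
pooled z with mean ≈ 0 and SD ≈ 1.02.

The default polynomial degree is 3 — enough curvature for the maturation
and senescence arcs of real spectra — and is recorded in the model so
alternative norms stay interchangeable. Degree is also the lever behind a
known limitation: near the extreme ages of the cohort, high-degree fits
extrapolate poorly and the SD surface gets noisy, so z-scores of subjects
at the very edges of (or outside) the age range are less calibrated;
evaluation outside the fitted range warns and flags extrapolation. The
parameter-recovery and calibration studies in the test suite fit
degree 1, matched to the synthetic generator's linear-in-log-age means,
because coefficient recovery is only a defined notion under a matched
parametrization; their tolerances (±0.05 on mean coefficients, ±0.03 on
SD) are checked on the averages across the 931 independent location-bin
fits, since at n = 211 the per-fit sampling SE is itself ≈ 0.04–0.05.

Scalp and source norms are independent instances of the same schema, and
the broad-band parameters can be z-scored through the same machinery with
a per-measure transform (log₁₀ for AP, logit for the bounded RP, identity
for MF). Norms serialize to a versioned JSON file (`qeegnorm-v1`) holding
all coefficients at full double precision; fitting can retain the
standardized residual fields for the empirical threshold below. Channel
matching between data and norms is by label, case-insensitive and
order-free; missing channels are an error, extra ones are dropped with a
warning. The package ships no population's coefficients — only the
fitter and a synthetic demonstration cohort.

## Multiple comparisons

A z-map tests hundreds of hypotheses at once, so thresholds are corrected
by the maximum-statistic criterion, two-sided (excess and deficit are
both meaningful). Two interchangeable rules are provided: the analytic
i.i.d. cutoff `t = Φ⁻¹((1 + (1−α)^{1/m})/2)`, exact under independence
and conservative under the positive dependence of real spectra, and an
empirical cutoff — the type-7 `1−α` quantile of per-field max |z| over at
least 20 null fields, typically the residual fields retained by the norms
fit — which adapts to the dependence and sits below the analytic value
when correlation is strong. Correction is joint over all locations × bins
by default (per-bin thresholds would answer a different question); the
pipeline applies whichever rule the configuration names.

## Synthetic data: what it emulates, and what it does not

The cohort generator mirrors the classical normative study conditions:
211 subjects, ages uniform on 5–87, eyes closed, 19 leads, 49 bins. Each
subject's log₁₀ spectrum is a deterministic mean surface — a `−log₁₀ f`
power-law background plus a Gaussian alpha peak near 10 Hz, both with
age coefficients linear in `u` so the surface lies inside the fitted
model family — plus i.i.d. Gaussian noise of SD 0.2 log₁₀-units, values
chosen as representative of between-subject spectral variability.
Spectra can be realized as time-domain epochs by inverse-DFT spectral
shaping (per-epoch random phases, cosine amplitude `√(2·power)`), which
reproduces the target periodogram *exactly* at every retained bin. The
dipole simulator projects a fixed-frequency oscillation through the lead
field and adds white sensor noise scaled to a target SNR at the
oscillation bin (default 20 dB, 24–50 epochs). Every generator is a pure
function of its spec and seed.

What passing tests therefore show: the estimators are correct and
calibrated *under the model they assume* — Gaussian log-residuals,
bin-aligned stationary oscillations, white sensor noise, a spherical
head. What they do not show: robustness to real EEG's 1/f fine
structure, non-stationarity, artifacts, correlated residuals across bins
and channels, or head-model mismatch. The generators make no attempt at
those, by design.

## Numerical conventions and problem sizes

Tolerances: Hermitian symmetry and positive semidefiniteness of
cross-spectra to 1e−9 relative; coherence clipped into [0, 1] only at the
1e−12 rounding level; ridge operators verified against dense solves to
1e−8; GCV ties broken toward the smaller λ; epoch text files round-trip
below 1e−6 µV, norms files below 1e−12 relative. The test suite sizes
its simulations for a desk machine: 1e5 Monte-Carlo draws for the
max-statistic quantile oracle (quantile SE ≈ 0.003 against a ±0.01
comparison), 2,000 null subjects for the family-wise error rate
(binomial SE ≈ 0.005), 50 seeded runs for dipole localization, and
211-subject cohorts for norm recovery — the whole suite runs in about a
minute.
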