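# qeegnorm

Quantitative EEG analysis with age-regression normative statistical
parametric maps, at the scalp and at reconstructed cortical sources.

## The problem

Clinical and research EEG is routinely summarized by its frequency
spectrum. A recording by itself, however, says little: spectral power
changes by orders of magnitude across the lifespan, and recording gain
varies between devices and subjects. The classical quantitative-EEG (qEEG)
answer is to compare each subject against an age-appropriate *normative
database*: every log spectral value is turned into a z-score,

    z(c, f) = ( y(c, f) − μ(c, f; age) ) / σ(c, f; age),

where `y` is the log₁₀ power at location `c` (electrode or source voxel)
and frequency bin `f`, and `μ`, `σ` are the normative mean and standard
deviation — smooth regression functions of age fitted on a healthy cohort.
Maps of these z-scores (normative statistical parametric maps) localize
excesses (e.g. pathological slow-wave activity over a lesion) and deficits
relative to healthy peers. `qeegnorm` implements this workflow end to end
for users who want an open, scriptable, fully inspectable version of it:

* **Narrow-band spectral model** — epoch-averaged cross-spectral matrices
  by FFT on the classical fine grid (0.39 Hz spacing, 0.39–19.11 Hz
  displayed labels for 2.56-s epochs at 200 Hz), plus magnitude-squared
  coherence and phase differences between all leads.
* **Broad-band model** — Absolute Power, Relative Power and Mean Frequency
  for the Delta/Theta/Alpha/Beta bands and their Total.
* **Global Scale Factor (GSF)** — a subject-level multiplicative gain on
  power, estimated as the grand-mean log deviation from the norms and
  removed so z-maps reflect spectral *shape*, not amplifier calibration.
* **Source imaging** — an analytic spherical-head lead field and a
  ridge-regularized distributed inverse (`T = Kᵀ(KKᵀ + λI)⁻¹`, λ by
  generalized cross-validation), transporting the scalp cross-spectrum to
  per-voxel source power spectra; optional standardized (resolution-
  normalized) source maps for localization.
* **Normative models** — per-location, per-bin polynomial regressions of
  the mean and SD of log spectra on log₁₀(age), fitted from a cohort,
  serialized to a versioned JSON norms file, and evaluated at any age.
* **Multiple-comparison control** — two-sided maximum-statistic |z|
  thresholds (analytic i.i.d. closed form and an empirical variant from
  normative residual fields) controlling the family-wise error rate
  jointly over all locations × bins.
* **Synthetic data** — seeded generators for normative cohorts with
  age-dependent spectra (optionally realized as time-domain epochs) and
  single-dipole scalp recordings at a target SNR, so the whole pipeline is
  testable without patient data.

Norms fitted by the package are synthetic demonstrations; the package
ships the *fitter*, not any population's coefficients.

## Worked example

Fit norms on a synthetic 211-subject cohort (ages 5–87, eyes closed),
then push one fresh subject through the full pipeline:

```r
library(qeegnorm)

spec  <- cohort_spec()                       # 211 subjects, ages 5-87, EC
coh   <- make_cohort(spec, seed = 7)
norms <- fit_norm_model(cohort_response_matrix(coh), coh$ages,
                        spec$grid, spec$channel_labels, degree = 1)
norms
#> <norm_model> scalp/EC: 19 locations x 49 bins, degree-1 polynomial in log10(age)
#>   fitted on 211 subjects, ages 5.6897-86.7297 y

subj <- make_cohort(cohort_spec(n_subjects = 1), seed = 42, realize = "epochs")
cfg  <- run_config(subj$epochs[[1]], gsf = TRUE, scalp_norms = norms,
                   leadfield = "spherical", lambda = "gcv",
                   correction = "maxstat-iid", seed = 3)
res  <- run_pipeline(cfg)
res
#> <qeeg_result>
#>   narrow band: 19 channels x 49 bins; broad band: 5 bands
#>   GSF log10 -0.0275
#>   source spectra: 257 voxels
#> <z_maps> scalp level, 19 locations x 49 bins, age 80.0141 y
#>   corrected |z| threshold 4.033 (alpha 0.05, analytic_iid): 0 suprathreshold

head(tidy(res$z_scalp), 3)
#> # A tibble: 3 x 4
#>   location frequency      z significant
#> 1 Fp1           0.39 1.24   FALSE
#> 2 Fp2           0.39 0.932  FALSE
#> 3 F3            0.39 0.0551 FALSE
```

Reading the output: the subject's estimated GSF is 10^(−0.0275) ≈ 0.94 —
their recording runs ~6% below the normative gain, and that factor is
divided out before z-scoring. The corrected threshold |z| ≥ 4.033 is the
two-sided maximum-statistic cutoff for 19 × 49 = 931 simultaneous
comparisons at family-wise α = 0.05; a healthy in-model subject shows, as
here, no suprathreshold bins. `autoplot(res$z_scalp)` draws the z-map with
the bipolar palette (deficit blue, excess red), `plot_topomap()` draws
interpolated scalp maps, and `export_maps(res, "outdir")` writes every
measure as a tidy CSV plus a JSON provenance record.

A command-line wrapper over the same functions is in
`inst/cli/qeegnorm.R` (subcommands `run`, `fit-norms`, `synth-cohort`,
`synth-dipole`).

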