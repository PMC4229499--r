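# subdcm

Dynamic causal modelling (DCM) of MEG evoked fields for adjudicating between
two architectures of rapid face processing: a **dual-route** network in which
the pulvinar projects directly to the amygdala alongside the cortical
LGN → V1 → amygdala pathway, and a **cortical-only** network without that
subcortical shortcut. The package is aimed at researchers who want a
self-contained, testable implementation of the full evidence chain —
biophysical forward simulation, sensor preprocessing, Bayesian model
inversion, and group-level model comparison — runnable end to end on a
synthetic cohort, since no recorded cohort is distributed.

## What it computes

* **Model space** — eight equivalent-current-dipole sources (bilateral LGN,
  V1, pulvinar, amygdala at literature MNI priors), two families
  (dual-route vs cortical-only) × four valence-modulation patterns, plus
  architecture variants (interhemispheric coupling, midline merging,
  intrinsic amygdala gain).
* **Neural-mass dynamics** — each source is a three-population convolution
  microcircuit: kinetics \(\ddot v = (H/\tau)u - (2/\tau)\dot v - v/\tau^2\),
  zero-centred firing sigmoid, forward afferents onto the input population,
  backward afferents onto principal and inhibitory populations, 16 ms
  conduction delays, RK4 integration (Rcpp).
* **Forward model** — the closed-form single-sphere conductor solution for
  a CTF-like array of 274 axial gradiometers, with a deep-source
  sensitivity simulation (the pulvinar is the least visible structure).
* **Preprocessing** — 0.5–30 Hz zero-phase Butterworth band-pass,
  600 → 200 Hz downsampling, −200..600 ms epochs, baseline correction,
  robust (bisquare-weighted) trial averaging, sensor-of-interest selection
  (sustained ≥ 25 ms response within 0–300 ms), 150–190 ms paired
  condition contrasts.
* **Inversion** — `dcm_fit()`, a variational-Laplace fit returning a
  classed object with `coef`, `vcov`, `predict`, `simulate`, `residuals`,
  `plot`, `summary` methods; the Laplace free energy is the per-subject
  model evidence.
* **Group inference** — random-effects Bayesian model selection (Dirichlet
  posterior, exceedance probabilities), family-level pooling, a window
  sweep over growing post-stimulus intervals, and the pulvinar→amygdala
  contribution (perturbation) analysis with increment 0.0025.
* **Synthetic cohorts** — `generate_cohort()` emulates the full experimental design
  (12 subjects × 3 conditions × 99 trials × 274 sensors at 600 Hz) with a
  seeded ground truth, trial jitter, sensor noise at a configured SNR, and
  outlier trials; `scaled_down_config()` is the desk-scale version.

## Worked example

```r
library(subdcm)

src <- build_source_set()
dipole_distance(src["V1.L", ], src["V1.R", ])    # 14 (mm) — the V1 pair
dipole_distance(src["LGN.L", ], src["PUL.L", ])  # 16.67 — LGN to pulvinar

# a desk-scale study: synthesize, preprocess, fit both families over three
# windows, compare them, and perturb the pulvinar-amygdala connection
cfg <- study_config(cohort = scaled_down_config(truth = "dual_route"),
                    seed = 1)
res <- run_study(cfg)
res$sweep$family
#>   window        family   expected   exceedance
#> 1    180    dual_route 0.91666667 0.9995117188
#> 2    180 cortical_only 0.08333333 0.0004882812
#> ...
```

The family table reads: at the earliest analysis window (0–180 ms) the
dual-route family has expected frequency ≈ 0.92 across subjects and
exceedance probability ≈ 0.9995 — the generating architecture is identified
essentially with certainty, because only the dual route can produce the
early amygdala deflection present in the data. `plot(res$sweep)` draws the
exceedance curves; `plot(res$contribution)` shows how a small enforced
increase (0.0025) of the pulvinar→amygdala log-gain changes source
activity, with the amygdala affected far more than the geniculate and the
pulvinar effect mediated entirely by amygdala feedback.

Single-subject fits expose the usual modelling verbs:

```r
fit <- res$fits[[1]]          # a dual-route fit, 0-300 ms window
summary(fit)                  # posterior means/SDs, free energy
coef(fit)["F.PUL.L>AMY.L"]    # pulvinar->amygdala forward log-gain
plot(fit)                     # data vs prediction per spatial mode
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
generates the desk-scale dual-route cohort at the given seed, preprocesses
it, fits both model families over the window sweep, runs the family-level
random-effects comparison and the contribution analysis — and writes its
JSON result to `--out` (a report bundle with the sweep tables and figures
is written alongside):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
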