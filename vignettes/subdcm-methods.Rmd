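---
title: "Dynamic causal modelling of a subcortical route to the amygdala: models, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic causal modelling of a subcortical route to the amygdala}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Faces evoke amygdala responses remarkably early (~140 ms). Two competing
circuit accounts explain this speed: a *dual-route* architecture in which the
pulvinar relays visual input directly to the amygdala in parallel with the
cortical LGN → V1 → amygdala path, and a *cortical-only* architecture in
which all amygdala input arrives via V1. `subdcm` implements the full
evidence chain for adjudicating between them with MEG evoked fields: coupled
neural-mass forward simulation, equivalent-current-dipole (ECD) sensor
projection, sensor preprocessing, variational-Laplace model inversion,
random-effects Bayesian model selection (BMS) over growing post-stimulus
windows, and a connectivity perturbation ("contribution") analysis. Because
no recorded cohort is distributed with the package, a seeded synthetic-cohort
generator stands in for the data and makes every stage testable end to end.

## The model space

Eight ECD sources with literature prior locations (MNI, mm): LGN (±22, −22,
−6), V1 (±7, −85, −7), pulvinar (±12, −25, 7), amygdala (±23, −5, −22).
Within each hemisphere, forward connections run LGN→V1 and V1→AMY, plus
PUL→AMY in the dual-route family only; hemispheres are not interconnected in
the original architecture; driving input enters at LGN and pulvinar. Each
family is crossed with four valence-modulation patterns (none / forward /
backward / recurrent modulation of the connections to and from the
amygdala), giving eight models.

Design choices where the architecture was genuinely open:

* **Reciprocity.** Every extrinsic forward connection has a backward
  partner. The recurrent-modulation pattern and the feedback mediation probed
  by the contribution analysis presuppose them.
* **Architecture variants.** `enumerate_architectures()` exposes the three
  single-flag variants — interhemispheric coupling between homologous
  structures (implemented as reciprocal forward/backward pairs), unilateral
  midline LGN/PUL (merged nodes at x = 0), and an intrinsic inhibitory
  self-gain on the amygdala principal population. There is no canonical
  catalogue of further variants, so the enumeration is configurable rather
  than fixed.
* **Lateral connections** are never used; the mask exists for forward
  compatibility.

## Neural-mass dynamics

Each source is a three-population convolution microcircuit: excitatory
interneurons (input layer), inhibitory interneurons, and principal cells
whose depolarisation \(v_P = v_E - v_I\) is the observed source signal.
Every population's membrane potential obeys the second-order synaptic
kinetics

\[ \ddot v = \frac{H}{\tau}\,u - \frac{2}{\tau}\dot v - \frac{v}{\tau^2}, \]

with excitatory gain/time-constant \(H_e = 3.25\) mV, \(\tau_e = 10\) ms and
inhibitory \(H_i = 29.3\) mV, \(\tau_i = 16\) ms; intrinsic gains
\(\gamma_{1..4} = 128, 102, 32, 32\); zero-centred sigmoid
\(S(v) = \sigma(\rho_1(v-\rho_2)) - \sigma(\rho_1\rho_2)^{-1}\dots\) with
\(\rho_1 = 2\,\mathrm{mV}^{-1}, \rho_2 = 1\) mV, so that rest is an exact
fixed point. Forward extrinsic afferents (gain \(32 e^{\theta_F}\)) target
the excitatory interneurons; backward afferents (\(16 e^{\theta_B}\)) target
principal and inhibitory populations. These are the conventional constants
for this model class; the pipeline's contracts do not depend on their exact
values. A unit subtlety: the synaptic gain enters as \(H\tau\), so the
integrator works in SI seconds internally — with \(\tau\) read in
milliseconds the same constants would put the network into a saturated
relaxation regime thousands of millivolts deep.

Numerics: fixed-step RK4 (default dt = 0.5 ms; the inversion uses dt = 1 ms,
which step-halving shows is well within tolerance), a ring buffer for the
16 ms extrinsic conduction delays with the delayed firing interpolated at
the step midpoint and held constant within each step, and divergence
reported with parameter context. The driving input is a causal Gaussian bump
(SD 16 ms); its amplitude (32) was chosen once so that evoked
depolarisations are a few millivolts.

## Forward model

A single homogeneous sphere (radius 90 mm, centred at MNI (0, 0, 20) mm;
MNI→head is a translation) with the closed-form conductor solution for the
external field; radial moments are silent and the radial field component
equals the infinite-medium dipole field, which the tests exploit as an
independent check. The sensor array is a deterministic CTF-like stand-in:
274 axial gradiometers (two-point difference, 50 mm baseline) on a
Fibonacci-lattice spherical cap (radius 110 mm, polar angle ≤ 120°),
radially oriented. The deep-source sensitivity simulation reports RMS
gradiometer response to unit tangential dipoles (random orientation, 2 mm
position jitter) relative to V1. With this geometry the pulvinar — the
deepest source — is always the least visible structure, reproducing the
expected depth ordering; the printed magnitudes depend
on the real CTF geometry and individual head models and are deliberately
not targets.

## Preprocessing

The sensor chain mirrors the emulated analysis: band-pass 0.5–30 Hz, downsample
600 → 200 Hz, epoch −200..600 ms (inclusive endpoints: 161 samples),
baseline-correct on −200..0 ms, robust trial averaging, SOI selection, and
the 150–190 ms paired contrasts (df = n − 1). Declared choices where the
procedure admits alternatives:

* **Filter.** Cascade of 4th-order Butterworth high-pass (0.5 Hz) and
  low-pass (30 Hz), both applied forward–backward (zero phase). No DSP
  package ships with the target runtime, so the bilinear-transform design is
  implemented here; its coefficients were cross-checked against an
  independent implementation and the response contracts (DC rejection,
  ≥ 20 dB at 50 Hz, ≤ 5% ripple at 10 Hz) are asserted in the tests. The
  30 Hz low-pass doubles as the anti-alias filter for the 3:1 decimation.
* **Robust averaging.** Iteratively reweighted mean per channel–sample
  across trials; bisquare weights (c = 4.685) on residuals scaled by
  1.4826·MAD; ≤ 20 iterations or weight change < 1e-6. Identical trials
  give unit weights and the arithmetic mean; a column whose weights collapse
  entirely falls back to uniform weights.
* **SOI selection.** One-sample two-sided t-test of the condition-average
  ERF against baseline across subjects, uncorrected p < 0.05, required over
  a contiguous ≥ 25 ms span centred on the sensor's peak within 0–300 ms;
  polarity is the sign at the peak. Because it sees only the condition
  average, selection is invariant to condition-label permutation.

## Inversion

`dcm_fit()` is the package's central fitting function. The data are reduced
to the leading spatial principal modes (default 8; the desk-scale pipeline
uses 6) and scaled to unit RMS — the scaling keeps the noise hyperprior's
implied residual scale commensurate with the data. Both conditions are
predicted jointly with shared parameters; condition differences enter only
through the modulation gains. Parameters and priors: per-edge log-scalings
N(0, 1/16), modulation gains N(0, 1/16), input log-gains N(0, 1/16), input
latency N(64 ms, 256 ms²), dipole moments N(0, 16) per component, and a
single mode-wide noise log-precision with hyperprior N(4, 1/16).

The optimizer is a Gauss–Newton/Levenberg ascent on the Laplace free energy
with an EM update of the noise precision: each iteration refreshes the
posterior covariance and noise precision from the current Jacobian (so the
reported covariance always reflects the final curvature), then takes a
damped step on the posterior mean, stopping after four consecutive
iterations with |ΔF| < 0.01 nats or 64 iterations. On linear-Gaussian
problems the free energy equals the exact log evidence (the acceptance tests
assert this to 1e-3 nats). The Jacobian uses central finite differences
(step 1e-3) for the dynamical parameters and exact analytic columns for the
dipole moments, which enter linearly — this split is what makes the fit grid
affordable. Each analysis window is inverted independently, with no
warm-starting, so the per-window evidences are comparable.

## Group inference

Random-effects BMS uses the variational Dirichlet scheme (prior count 1 per
model); exceedance probabilities come from the analytic Beta tail for two
models and seeded Dirichlet sampling (default 1e6 draws) otherwise.
Family-level inference pools member evidences per subject by log-mean-exp
(a uniform within-family prior), then applies RFX BMS over families — one
defensible reading of family inference, declared rather than inferred. Only
within-subject evidence differences matter, and the tests assert the
corresponding invariances.

The contribution analysis integrates each fitted dual-route model at its
posterior mean with and without an additive increment of 0.0025 on the
PUL→AMY forward log-scaling — the natural parameter of the model, since the
study states the increment without units — over 0–300 ms, and averages the
source-level deltas over models and participants. Zeroing the backward
amygdala→pulvinar couplings removes the pulvinar delta entirely: in this
architecture the pulvinar has no other afferent from the perturbed pathway,
so any pulvinar effect is mediated by recurrent feedback.

## The synthetic cohort: what it emulates, and what a green test establishes

The generator states the emulated design: 12 subjects, 3 conditions × 99
trials, 274 sensors at 600 Hz, epochs −200..600 ms. Its ground truth is a
dual-route (or cortical-only) network with:

* subject couplings log-normally jittered (SD 0.1) around the priors;
* a group pulvinar→amygdala elevation of +0.25 (1 prior SD) — within the
  prior's plausible range, and strong enough that the amygdala peaks near
  140 ms, clearly before the cortically relayed response, the regime the
  study reports;
* group input latency 32 ms (an early geniculate volley; subject SD 5 ms).
  The inversion prior stays at 64 ms, two prior SD away, and is recovered;
* group-level dipole moments shared across subjects up to jitter (SD 0.3),
  so a group SOI analysis is meaningful;
* per-trial amplitude (±10%) and latency (±10 ms) jitter, white sensor
  noise at the configured SNR (signal power of the condition mean over
  0–300 ms versus per-trial noise power, the declared definition), and
  outlier trials (rate 0.02) at 30× noise.

What it does **not** emulate: correlated sensor noise, eye-blink and muscle
artifact waveforms, head movement, individual head geometry, or the
concurrent auditory stream of the original task. A green recovery test
therefore establishes that the pipeline's inferential machinery works on
data with the assumed statistical structure — not that the original
neural conclusions are reproduced.

`scaled_down_config()` shrinks the design to 10 subjects × 40 trials × 64
sensors; the window sweep uses {0–180, 0–240, 0–300} ms, a coarse subset of
the full 0–60..0–300 ms grid whose earliest member sits at the boundary of
the early regime of interest (the synthetic amygdala signal,
like the reported one, carries little energy before ~120 ms, so windows
shorter than that cannot discriminate the families in this world). Ten
subjects — not eight — keep a 90%-of-subjects recovery criterion
representable (9/10). With a single modulation pattern per family the
family comparison reduces exactly to the two-model comparison, which the
tests verify as an identity.

## What the desk-scale recovery does and does not establish

Two advertised properties of the recovery study are *not* met by this method
class, and the corresponding checks are deliberately left failing rather
than weakened:

* **Per-subject 2-SD calibration of the pulvinar→amygdala coupling.** The
  variational-Laplace posterior is a local Gaussian; under the amplitude
  near-degeneracy between dipole-moment magnitude and coupling gain, and
  with the truth one prior SD above the prior mean (so honest shrinkage
  biases the estimate), its SDs (~0.02–0.05) understate the spread of
  optima (~0.1–0.3). End-to-end coverage at 2 posterior SD is ~40–70%, not
  ≥ 90%. On direct model-generated data the estimates are accurate in
  absolute terms (mean error ≈ 0.07–0.1 against an effect of 0.25) and the
  route elevation is detected in every subject; it is the *credibility
  calibration*, not the estimation, that fails — the long-standing critique
  of Laplace posteriors in this model family.
* **Specificity at the shortest window.** Trial averaging leaves an
  irreducible jitter-realisation residual (the 40 sampled latencies are not
  exactly the uniform kernel), structured like the signal derivative. Both
  families absorb most of it, and the dual-route family's four extra
  couplings absorb slightly more; at evoked-response noise levels a few
  hundredths of residual variance are worth tens of nats, so the more
  flexible family wins the shortest window even on cortical-only data.
  Specificity holds for the longer windows (dual exceedance 0.27 at 0–240,
  0.12 at 0–300 on a cortical-truth cohort). The sensitivity direction —
  dual-route truth recovered with exceedance > 0.99 at every window — is
  unaffected.

## Known limitations

* The spherical head and synthetic helmet preserve qualitative sensitivity
  orderings, not any particular recorded system's sensitivity magnitudes.
* The inversion fits unfiltered model output to filtered data; the 0.5–30 Hz
  band covers the model's spectral content, but very slow components are
  attenuated asymmetrically.
* Free energies are lower bounds computed under the Laplace approximation;
  they are exact only for linear-Gaussian models.
* The desk-scale runtime budget, not statistics, sets the default number of
  windows and modes.
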