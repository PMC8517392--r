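---
title: "Non-invasive pressure-strain loop myocardial work: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive pressure-strain loop myocardial work: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pslwork)
```

## The measurement problem

Global longitudinal strain (GLS) from speckle-tracking echocardiography is a
sensitive index of left ventricular systolic function, but it is
load-dependent: the same myocardium deforms less against a higher afterload.
The pressure-strain loop (PSL) method corrects for this by pairing each
segment's longitudinal strain $\varepsilon(t)$ with an estimate of the
instantaneous left ventricular pressure $P(t)$, and integrating their product
rate over the cardiac cycle. The area of the resulting loop is myocardial
work in mmHg·%, a load-adjusted index of contractile performance. This
package implements the full chain for a two-group clinical study design
(normal controls versus type 2 diabetes): pressure-curve construction, work
quantification, a calibrated synthetic cohort generator, and the statistics
layer used to compare groups and identify risk factors.

## Non-invasive pressure curve

Measuring $P(t)$ directly requires catheterization. The non-invasive
alternative scales a fixed, normalized reference pressure profile to the
individual subject:

* **Time axis.** The profile is defined on phase-normalized time: one unit
  each for isovolumic contraction (mitral valve closure MVC to aortic valve
  opening AVO), ejection (AVO to aortic valve closure AVC) and isovolumic
  relaxation (AVC to mitral valve opening MVO). Each phase is independently
  and affinely stretched onto the subject's own valve-event timings, which
  are inputs (in practice read off Doppler spectra).
* **Amplitude.** The profile peak is scaled to the brachial cuff systolic
  pressure, under the standard assumption that peak systolic LV pressure
  equals peak arterial pressure in the absence of outflow obstruction.

The reference shape itself is a piecewise raised-cosine template
(`build_reference_curve()`): a half-cosine rise from 0 at MVC to 0.90 at
AVO, a cosine arch peaking at 1 at 30% of ejection and falling to 0.55 at
AVC, and a half-cosine decay to 0.10 at MVO. These anchor values are a
documented design choice: they reproduce the qualitative LV pressure
morphology (slow isovolumic build-up, rounded early-systolic peak, rapid
isovolumic fall) while making every phase boundary exactly testable. The
shape is a named constant and can be swapped for a different template
without touching the rest of the engine. Two further choices are explicit:

* the curve is anchored at 0 mmHg at MVC and is not offset by diastolic
  cuff pressure (only the peak is pinned by the cuff measurement; an
  explicit zero baseline beats a hidden one), and
* the curve's domain ends at MVO, because every work index integrates over
  the MVC-to-MVO window only.

Sampling uses at least 1025 points per phase (default step: cycle span /
2000), which keeps linear-interpolation error below $10^{-6}$ of the
systolic pressure; the exact ejection-peak instant is always included so
the sampled maximum equals the cuff pressure to machine precision.

```{r pressure}
ev <- valve_events(0, 0.06, 0.36, 0.44)
curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(120, 78))
curve
plot(curve$times, curve$pressures, type = "l", xlab = "time (s)",
     ylab = "pressure (mmHg)")
abline(v = c(ev$t_avo, ev$t_avc), lty = 3)
```

## Work quantification

With strain in percent (negative = shortening), instantaneous myocardial
power is defined as

$$ w(t) = -\frac{d\varepsilon}{dt}\, P(t), $$

so that physiologic shortening under pressure yields positive work. Strain
rate uses central differences (second-order one-sided stencils at the
endpoints, exact for quadratics), both signals are resampled onto a common
uniform grid over [MVC, MVO] by linear interpolation, and integrals use the
trapezoid rule. The segmental indices follow the phase rules of the PSL
method:

* **systole** (MVC to AVC): shortening is *constructive*, lengthening is
  *wasted*;
* **isovolumic relaxation** (AVC to MVO): the roles invert — lengthening is
  constructive, post-systolic shortening is wasted.

Formally the engine integrates the phase-adjusted power
$v(t) = \sigma(t)\,w(t)$ with $\sigma = +1$ in systole and $-1$ in IVR:
constructive work is $\int \max(v, 0)\,dt$, wasted work is
$\int \max(-v, 0)\,dt$, and the segmental work index is their difference.
This makes the decomposition identity *exact by construction* — net work
always equals constructive minus wasted — which in turn makes the global
indices internally consistent: GWI = GCW − GWW for every subject. (A
consequence worth knowing: definitions of GWI that integrate the raw,
sign-unadjusted power over the whole window differ from this one whenever
IVR lengthening occurs; we chose the decomposition-exact convention.)

Global indices aggregate the 17 standard segments: GWI/GCW/GWW are
arithmetic segment means (a mass-weighted variant would drop in via the
same interface; the equal-weight mean is the simplest auditable choice),
GWE $= 100\,\mathrm{GCW}/(\mathrm{GCW}+\mathrm{GWW})$, and GLS is the
weighted mean of the 17 peak systolic strains (minimum strain over
[MVC, AVC]) with equal weights by default, the apex counted once.

### Numerical behavior

* The default integration grid (cycle/2000) is far below the strain frame
  interval (≈ 1/65 s at typical frame rates of 57-68 fps), so accuracy is
  strain-resolution-limited: halving the step changes the large integrals
  by well under 0.1%.
* The phase boundary at AVC is handled at the difference-stencil level: a
  sample switches to the IVR sign only when its whole stencil lies past
  AVC. For a trace that is linear in systole and flat afterwards this makes
  the constant-pressure oracle exact (work $= P\,|\Delta\varepsilon|$ to
  machine precision, zero waste). For traces that begin lengthening
  immediately after AVC a discretization residue of order 0.01 mmHg·%
  (≈ 0.001% of GCW) can appear in the wasted channel.
* Wasted work is a small difference quantity assembled from narrow
  strain-rate reversals; under grid refinement it is therefore compared on
  the scale of the segment's total handled work, while the net and
  constructive integrals agree to 0.5% directly.

## The synthetic cohort generator

No patient data ship with the package; the generator produces cohorts with
the statistical structure the analysis layer assumes, so every downstream
stage is testable end to end. It emulates a 50-versus-50 normal-control /
T2DM echocardiography study.

**Covariates.** Normally reported covariates (age, BMI, BSA, blood
pressures, heart rate, lipids, HbA1c, and in the diabetic group fasting and
post-prandial glucose) are truncated normals with the published group means
and SDs; skewed covariates (HDL-C, diabetes duration) are log-normals
matched to the published median and interquartile range; sex and smoking
are Bernoulli with the published proportions. Truncation implements the
study's exclusion criteria (notably SBP 90-140 mmHg, reflecting the
no-hypertension rule) and physiologic guards elsewhere. Pulse pressure is
derived as SBP − DBP. An ejection-fraction analogue is drawn from the same
distribution in both groups, mirroring the study's null finding for LVEF.

**Traces.** Each segment's strain is a raised-cosine contraction profile on
a 65 Hz frame grid: zero at MVC, peak at AVC, partial recovery
(lengthening) during IVR (default recovered fraction 0.15). Two
perturbations produce realistic wasted work: (i) smooth measurement-like
noise — a random 3-sinusoid mixture in the 5-14 Hz band, tapered to zero at
the window ends — whose local strain-rate reversals generate wasted work
the way speckle-tracking noise does; and (ii) with per-segment probability,
an explicit post-systolic-shortening dip early in IVR. Noise amplitudes
(SD 1.1% NC, 1.0% T2DM) and PSS parameters (probability 0.15/0.40,
amplitude SD 1.5/2.0%) were calibrated once so that cohort medians of GWW
and GWE approximate the published group summaries (≈ 33 vs ≈ 50 mmHg·%,
≈ 98.5 vs ≈ 97.4%), and then frozen.

**Severity structure.** In the diabetic group a latent severity variable

$$ s = \beta_1 z(\mathrm{HbA1c}) + \beta_2 z(\mathrm{duration}) +
      \text{residual} $$

scales all segmental peak strains multiplicatively, with configured
standardized effects $\beta_1 = -0.45$ and $\beta_2 = -0.30$ on the
constructive-work channel (values taken from the multivariable analysis of
the motivating study as calibration targets, not ground truth). Both
inputs are standardized against their specification-level (not sample)
moments; duration is standardized on its truncated raw scale (years) so
that the regression layer, which uses years as the predictor, recovers the
configured coefficients — a log-scale latent would attenuate recovery
through the duration distribution's heavy tail. The loadings carry a fixed
calibration factor (1.03) compensating the dilution of realized
standardized coefficients by additive work components, and the residual
share is sized so the total relative SD of the work channel stays at its
configured value after accounting for the variance contributed by cuff SBP
and by 17-segment averaging. Because the latent acts on the common work
scale, it also loads on GWI and GLS — separating a "GCW-only" effect is
not possible in trace space, since GWI = GCW − GWW ties the channels
together.

**Reproducibility.** One master seed governs everything; per-subject RNG
substreams are derived by stable hashing of the subject id, so a subject's
data do not depend on cohort size or generation order, and equal seeds
give byte-identical cohorts.

What the generator deliberately does **not** model: image formation and
speckle tracking itself, regional (per-segment) disease patterns,
inter-segment correlation beyond the shared subject scale, heart-rate
dependence of phase durations, repeat visits, and treatment effects.
Passing tests therefore demonstrate that the pipeline recovers structure
that is present by construction — they do not validate the PSL method
against invasive measurements or real patients.

## Statistics layer

The comparison layer reproduces a standard two-group clinical analysis:

* **Pooled-variance Student t** (not Welch), from raw samples or directly
  from printed group means/SDs. The pooled variant is the one that
  reproduces the internally consistent published table statistics from
  their own summary rows.
* **Mann-Whitney U** with normal approximation, tie-corrected variance and
  0.5 continuity correction, signed so that a smaller group-1 (NC)
  distribution gives negative Z, matching clinical table conventions; an
  exact-enumeration mode is available for small tie-free samples.
* **Pearson chi-square without continuity correction** on 2×2 tables —
  again the variant consistent with the published categorical rows.
* **Pearson correlation** with t-based p-values.
* **Linear regression with standardized coefficients**
  ($\beta^{std} = b\,\mathrm{sd}(x)/\mathrm{sd}(y)$; in a univariable fit
  this equals Pearson's r), plus **stepwise selection** by p-value
  (forward entry at $p < 0.05$, backward removal at $p > 0.10$ — the
  conventional thresholds, since only "stepwise selection" is specified in
  such analyses; candidates are pre-filtered to univariable $p < 0.05$).
  Ties break deterministically by candidate order.
* **Bland-Altman agreement**: bias = mean paired difference, limits of
  agreement = bias ± 1.96 SD. The pipeline emulates the intra-/
  inter-observer design by re-measuring a random subset of subjects with
  configurable Gaussian re-measurement noise.

Routing of variables to t versus Mann-Whitney is configuration, defaulting
to the usual layout (skewed HDL-C, LVEF analogue, GLS, GWW, GWE to the
rank test). Two-sided p-values and a 0.05 significance threshold are used
throughout; no multiple-testing correction is applied, matching the
single-study design.

## Problem sizes used in validation

The shipped validation suite exercises the documented claims at the
following scales, chosen to estimate each quantity comfortably: exact
statistic reproduction from printed summaries (n = 50 + 50 closed-form);
work-engine oracles on single traces with 16-fold grid refinement; the
decomposition identity on 1,000 generated segments; effect recovery on a
single diabetic group of n = 1,000 plus 100 replicate null groups of
n = 100; and direction reproduction on 100 replicate 50-versus-50 cohorts.
`scripts/acceptance.R` re-runs a compact version of the same surface from
a fresh seed.

## Known limitations

* The reference pressure template is a stand-in with documented anchors,
  not the proprietary profile used by clinical workstations; absolute work
  values therefore differ from vendor output by a shape factor, while
  group contrasts and all internal identities are unaffected.
* GWI equals GCW − GWW by construction here; published tables whose GWI,
  GCW and GWW are mutually inconsistent under that identity cannot all be
  matched simultaneously, and the generator is calibrated to GLS, the GWW/
  GWE medians and the work-index scale.
* Equal segment weights for GLS ("weighted average" with unspecified
  weights in the field's descriptions) and subject-level GWE aggregation
  are explicit choices, both exposed as parameters.
* The Mann-Whitney exact mode requires tie-free samples and $n \le 10$ per
  group; elsewhere the normal approximation is used regardless of size.
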