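---
title: "From force-distance curves to group stiffness: models and methods"
author: "afmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force-distance curves to group stiffness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmech)
```

## The measurement and its model

Contact-mode AFM on living cochlear cells records, for each approach ramp,
the piezo position $z$ (µm, increasing toward the sample) and the
cantilever deflection $d$ (µm). Before contact, $d$ follows a slowly
varying optical baseline; after the tip touches the surface at $z_0$, the
cantilever bends as the sample is indented. For a sharp pyramidal/conical
tip of half-angle $\alpha$ on an elastic, incompressible half-space, the
Sneddon solution links force and indentation:

$$F \;=\; \frac{2}{\pi}\,\tan\alpha\,\frac{E}{1-\nu^2}\,\delta^2 .$$

We work in µm, nN and kPa throughout; since $1\,\mathrm{kPa}\cdot
\mu\mathrm{m}^2 = 1\,\mathrm{nN}$, no unit constants appear anywhere in the
chain, and a spring constant quoted in N/m converts as
$1\,\mathrm{N/m} = 1000\,\mathrm{nN}/\mu\mathrm{m}$.

The printed formula for this prefactor is typographically ambiguous
("2/πtanα"); we read it as $(2/\pi)\tan\alpha$, the standard conical
Sneddon form in which stiffer response comes with blunter tips. Both
`sneddon_force()` and `fit_modulus()` accept `form = "inv-tan"` to select
the alternative reading $2/(\pi\tan\alpha)$, so results under either
convention can be produced; round-trip recovery is invariant to the choice
(and to $\alpha$ itself) as long as generation and fitting share it.

### Assumptions

* Linear elasticity, sharp rigid indenter, semi-infinite sample: no
  adhesion, no viscoelastic rate dependence, no finite-thickness
  (bottom-effect) correction.
* $\nu = 0.5$ (incompressible soft tissue) unless overridden.
* Only the approach segment is analysed; retract-curve hysteresis carries
  adhesion information that the stiffness estimate does not use.

## Curve processing

**Baseline removal.** A least-squares line through the first
`pre_fraction` (default 0.2) of samples is subtracted from the whole
trace. Four samples is the hard minimum for the fit.

**Contact-point detection.** For a candidate contact position $z_0$, the
trace is modelled as a flat baseline before $z_0$ and a Sneddon response
after it. The post-contact prediction uses the *implicit* deflection
model described under "Synthetic data" below, with the modulus profiled
out in closed form, so the candidate's score is a genuine two-regime
residual sum of squares. The search is deterministic: a coarse grid over
sample indices (about 128 candidates), an exhaustive fine pass around the
coarse winner, then a continuous 1-D minimization of the SSE over $z_0$
between neighbouring samples (`stats::optimize`, tolerance $10^{-10}$).
The continuous refinement matters: a contact point locked to the sampling
grid can sit half a sample spacing away from the true contact, which
propagates into a relative modulus bias of order $10^{-3}$ on a 1024-point
3-µm ramp — larger than the package's own noiseless-recovery tolerance.
Index ties resolve toward the smaller index, which biases the indentation
range high rather than clipping genuine contact data. If the best
piecewise model fails to reduce the SSE of the all-baseline model by
`contact_improvement_factor` (default 2), the curve is declared to have no
contact.

`process_curve()` runs detection twice: first on the raw curve with a
free-slope baseline (so a contact point that falls inside the nominal
pre-contact window cannot contaminate the detrend), then the detrend is
refit on confirmed pre-contact samples and detection repeats on the
detrended trace with the flat baseline.

**Conversion.** With contact $(z_0, d_0)$:
$F = 1000\,k\,(d-d_0)$ nN and $\delta = (z-z_0) - (d-d_0)$ µm — the
tip–sample separation convention, which corrects piezo travel for the
cantilever's own bending. Samples with $\delta < 0$ are dropped, the curve
is truncated at `delta_max` (default 1.5 µm, the maximum indentation used
for cochlear explants), and at least 8 post-contact samples must survive
(a quadratic fit needs headroom over noise).

## Modulus estimation and aggregation

The fit is least squares of $F$ on $\delta^2$ *through the origin*
(contact-point removal already pins $F(0)=0$), with the closed-form slope
$\hat c = \sum F_i\delta_i^2 / \sum \delta_i^4$ and
$\hat E = \hat c\,(\pi/2)\cot\alpha\,(1-\nu^2)$. $R^2$ is reported for
quality control; in `fit_dataset()` curves with $R^2$ below
`r2_threshold` (default 0.8) are discarded and logged, a discarded curve
simply reduces the per-cell average, and a cell with no surviving curves
is dropped with a warning — the group is never failed outright.

Aggregation mirrors the experimental scheme: the cell modulus is the
arithmetic mean of its (up to 3) curve moduli; the group summary is the
mean ± s.e.m. (sample sd/√n) over its cells (typically 10). Pairwise
group comparisons use Welch's unequal-variance t-test on the per-cell
moduli; the 0.05/0.01/0.001 star annotations are reporting conventions
only and never filter results. The companion morphometric, fluorescence
and qPCR comparisons use the pooled-variance Student test, matching the
practice of the experiments these operators reproduce. For qPCR we test
and aggregate on the ΔCt scale (fold change is derived afterwards as
$2^{-\Delta\Delta Ct}$), since Ct values are the quantity with
approximately normal replicate noise.

## Synthetic data

The generators exist to exercise the full chain against known truth, with
every dataset carrying a manifest (seed plus all parameters) sufficient to
regenerate it bit-exactly.

**Force curves.** Pre-contact deflection is `baseline_slope`·z; past the
contact offset the bending $d_b$ solves the force balance
$1000\,k\,d_b = F_{\mathrm{Sneddon}}(E, (z-z_0) - d_b)$ — the indentation
handed to the contact model is reduced by the cantilever's own bending,
rather than the common shortcut $\delta = z - z_0$. The equation is
quadratic in $d_b$ and solved exactly (stable root), which makes the rigid
limit testable: $d_b/s = 1 - \sqrt{K/(Cs)} + O(K/Cs)$, so the deflection
approaches piezo travel monotonically as $E$ grows, reaching 1% agreement
only near $10^6$ kPa at these spring constants — a regime the tests probe
at $E = 10^8$ kPa. Gaussian noise of `noise_sd` µm (default 2 nm, a
typical optical-lever noise floor) is added last.

**Experiments.** Per-cell moduli are Normal(group truth, `cell_sd`)
truncated at zero. The study reports only group mean ± s.e.m., so
`cell_sd` is a free design parameter; when a group's `sem` is supplied,
`cell_sd = sem·√n_cells` reproduces the reported dispersion. Contact
offsets are drawn uniformly from `contact_offset_range` (default
0.4–0.6 µm of a 3-µm ramp). Child seeds are derived from the design seed
by a deterministic integer hash of (group, cell, curve) indices, keeping
all seeds below $2^{31}$.

**Other generators.** Gel lanes are sums of Gaussian bands with
*specified analytic areas* on a linear background (band windows at ±5σ,
where the excluded tail mass is below $10^{-4}$ of the band); image
patches are piecewise-constant stripes with centred 2-µm windows; Ct
tables place the reference gene at `base_ct` everywhere and shift targets
by $-\log_2(\text{fold})$.

What these generators deliberately do not emulate: adhesion and
viscoelastic artifacts in curves, thermal drift, rolling-ball-shaped gel
backgrounds, camera point-spread functions, or qPCR efficiency deviations
from 2. Passing recovery tests therefore demonstrate the correctness of
the analysis chain under its own model assumptions, not robustness to
every artifact of real instruments.

## Numerical choices and degenerate inputs

* Contact SSE refinement tolerance $10^{-10}$ µm; implicit-solve closed
  form is exact to machine precision.
* Identical constant samples in the t-tests return $t=0,\ p=1$ (equal
  means) or $p=0$ (different means) instead of erroring.
* Rigid-surface curves ($d$ tracking $z$ exactly) are rejected at
  conversion for having no indentation range; non-positive fitted slopes
  are rejected as non-physical; all-equal $\delta$ is rejected as
  degenerate.
* Densitometry baselines are straight lines between window endpoints — a
  parameter-free, testable stand-in for interactive gel-analysis
  baselines; band areas use the trapezoid rule.
* Pixel inclusion in line-scan windows is by pixel centre; window extent
  along the scan axis must be 2 µm within half a pixel.

## Problem sizes used by the test suite

Deterministic recovery checks run on 1024-sample (occasionally
4096-sample) ramps. The Monte-Carlo unbiasedness check uses 100 replicate
experiments of 10 cells × 3 curves at 512 samples per ramp — at that
resolution the discretization bias of the recovered group mean is well
below the replicate scatter, which is what the check measures. The
null-size check of both t-tests uses 2000 simulated null datasets of 10
observations per group.

## Known limitations

* A fixed nominal tip half-angle (default 18°) must be supplied; probe
  batches vary, and $\hat E$ scales as $\cot\alpha$, so absolute moduli
  inherit that calibration uncertainty (comparisons within a calibration
  do not).
* No bottom-effect correction: very thin samples over glass will read
  stiff.
* The contact search assumes a single contact event per ramp; double
  contacts (debris, membrane tethers) will fit poorly and should be caught
  by the $R^2$ gate rather than recovered.
* `fit_dataset()` groups strictly by (condition, cell type, age); region
  (base/apex) is carried in metadata but not used as a grouping key.
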