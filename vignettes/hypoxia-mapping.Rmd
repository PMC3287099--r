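---
title: "Mapping chronic tumor hypoxia from vascular masks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping chronic tumor hypoxia from vascular masks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxymap)
```

## The problem

Chronic hypoxia in solid tumors arises where the diffusion range of
oxygen around sparse, poorly organized vasculature falls short of the
metabolic demand of the tissue. Because hypoxic cells are markedly more
radioresistant, the spatial distribution of oxygen in a tumor
cross-section matters for both prognosis and radiotherapy planning; yet
the clinical measurement techniques — polarographic needle electrodes
and nitroimidazole hypoxia markers — are invasive and sample the tumor
sparsely. `oxymap` simulates the oxygen field implied by a known map of
*perfused* vasculature, quantifies hypoxia the way each measurement
technique would, and asks how well those techniques recover the truth
they sample.

## Transport model

A tumor cross-section is a square domain (default 6 mm, 100 × 100
cells, 60 µm spacing) carrying co-registered binary masks: vessels,
perfusion, total tumor area and, optionally, a marker-derived hypoxia
mask for validation. The perfused-vessel indicator
$m_p(x) \in \{0, 1\}$ is the cellwise AND of the vessel and perfusion
masks; perfused vessels are the only oxygen sources.

Oxygen concentration $K(x,t)$ and tumor cell density $c(x,t)$ evolve by

$$\partial_t K = D_K \nabla^2 K + r\,m_p - \eta K - \phi\,c\,K, \qquad
  \partial_t c = D_c \nabla^2 c + \rho\,c\,(1 - c/c_{\lim}) +
  \gamma\,m_p\,c,$$

with no-flux boundaries on the square grid edge. Defaults:
$D_K = 2.5\times10^{-5}\ \mathrm{cm^2\,s^{-1}}$,
$r = 8.2\times10^{-3}\ \mathrm{s^{-1}}$ (model units of oxygen),
$\eta = 0$, $\phi = 3.8\times10^{-13}\ \mathrm{s^{-1}}$ per cell,
$D_c = 4.05\times10^{-9}\ \mathrm{cm^2\,s^{-1}}$,
$\rho = 1.85\times10^{-6}\ \mathrm{s^{-1}}$,
$c_{\lim} = 2.1\times10^{11}$, $\gamma = 2.96\times10^{-6}\
\mathrm{s^{-1}}$.

Three modeling points deserve emphasis.

* **Vessels are volumetric sources, not Dirichlet cells.** The supply
  term $r\,m_p$ literally injects oxygen at perfused cells; the vessel
  oxygen level is not pinned. The initial condition places `K_vessel`
  (default 1 model unit) on perfused cells and zero elsewhere.
* **Oxygen units are relative.** The literature values above mix units
  that cannot be made jointly consistent (the supply rate is quoted in
  oxygen units per second, the carrying capacity in "cells/s"), so the
  solver nondimensionalizes lengths by the grid spacing and time by
  $dx^2/D_K$ and treats $K$ in arbitrary model units, with
  $\tilde r = r\,dx^2/D_K$ and $\tilde\phi c = \phi\,c\,dx^2/D_K$ as
  the effective dimensionless supply and consumption. Every hypoxia
  statistic in the package is defined *relative* to the field maximum,
  so no absolute oxygen calibration ever enters a result. Two exact
  consequences are tested: the field is linear in $(r,\, K_{vessel})$
  jointly, and hypoxic fractions are invariant under that scaling.
* **The initial cell density is a whole-grid Gaussian.** $c_0$ is an
  isotropic Gaussian (default peak $c_{\lim}$, width 1.5 mm) centred at
  the tumor centroid and *not* truncated to the tumor mask. The tails
  give peritumoral tissue a small oxygen consumption, which is both
  physiologic (the surrounding stroma is not inert) and numerically
  important: with a consumption-free exterior, the outer grid acts as a
  reservoir that equilibrates only on the whole-domain diffusion
  timescale, and the hypoxic fraction drifts indefinitely at about the
  stationarity tolerance. The width is a configuration knob
  (`c0_sigma_mm`); the default of roughly a quarter of the domain makes
  consumption strongest in the tumor core.

### Numerical scheme

Explicit forward Euler with the five-point Laplacian and mirrored
(ghost-cell) edges; the default step is $0.2\,dx^2/(4 D_K)$ — a fifth
of the two-dimensional stability bound — so nonnegativity of both
fields holds by construction and is never enforced by clipping. The
stencil is conservative: in the source- and sink-free configuration the
grid total of $K$ is preserved to one part in $10^{12}$ per step (a
tested invariant). Oxygen and cell updates are operator-split per step,
with consumption evaluated against the previous step's cell density.
Three independent oracles pin the solver down: exact mass conservation;
the closed-form uniform balance $K \to r/(\phi c)$ under a uniform
source; and, on an effectively one-dimensional configuration (one fully
perfused grid row), agreement to $10^{-8}$ with a direct tridiagonal
solve of the stationary system.

### Stationarity of the relative hypoxic fraction

The simulation seeks a *snapshot* consistent with a fixed vascular map,
not a transient. Because hypoxia is defined relative to the evolving
field maximum, its area fraction settles long before the absolute field
does. The solver checkpoints the hypoxic fractions every 200 steps and
stops once every monitored threshold differs by less than `tol_hp`
(default 0.005) from its value at *half* the elapsed time, twice in a
row. This doubling test was chosen over a fixed-interval test
deliberately: checkpoint-to-checkpoint changes fall below any fixed
tolerance while the fraction is still climbing, whereas the doubling
test certifies directly that the reported fraction no longer depends on
the computational horizon. Typical domains reach stationarity in
3000–4500 steps (about 300 s of model time); the returned trace lets
callers audit the approach.

A domain with no perfused vessels is degenerate — every tumor cell is
hypoxic at any relative threshold — and is returned after a single
checkpoint with a flag rather than iterated to a vacuous steady state.

## Quantifying hypoxia

A cell is hypoxic at level $p$ when
$K < (p/100)\,\max_x K$, with the maximum taken over the whole grid
(configurable to the tumor mask). The standard levels HP2.5, HP5 and
HP10 correspond to severe, moderate and mild hypoxia. Threshold masks
are nested by construction and invariant to positive rescaling of the
field; both properties are tested. The *area method* reports the
fraction of tumor cells hypoxic; *spatial agreement* against a
reference mask is the percentage of tumor cells on which two masks
agree (a Jaccard overlap is available as an alternative).

## Virtual needle electrodes

Electrode measurements are simulated as linear tracks of readings
0.2 mm apart, 20–30 readings per track; one 60 µm grid cell is the
measurement volume of the tip, so a reading is simply the value of the
containing cell. Four placement strategies are provided: parallel
vertical tracks splitting the tumor bounding box evenly (*uniform*);
boundary entry points aimed at random interior points (*random*); and
radial fans aimed at the tumor centroid over a narrow 10-to-2-o'clock
arc (*half_radial*, arc configurable) or the full circle
(*full_radial*). Two geometric choices matter:

* **Radial needles stop at the centroid.** A radial track samples the
  segment from the tumor surface to the centre, not a full diameter.
  This is what confines a narrow-arc fan to one sector of the tumor —
  the stated reason radial sampling is the least accurate protocol —
  and it is also how a physical needle aimed at the centre of a tumor
  is used. Radial tracks therefore carry fewer readings when the radius
  is shorter than the nominal track length.
* **Readings outside the tumor are discarded** (when a tumor mask is
  supplied). A fixed-length track that overshoots the tumor would
  otherwise collect readings in unvascularized surrounding tissue,
  whose low simulated oxygen systematically inflates the electrode
  hypoxic fraction; a clinician reports tumor readings.

Pooled readings are converted to hypoxic fractions with the same
relative thresholds and the same global reference maximum as the area
method, so the two estimators are directly comparable. Simulated
electrodes carry no instrument error by default; optional Gaussian
noise (clamped at zero) is available for robustness studies.

## Variance-components analysis

Two questions are asked of a cohort of tumors. *How many tracks make a
single tumor's reading reliable?* One-way random-effects ANOVA on
pooled readings estimates the within-tumor mean square $MS_w$ and the
between-tumor component $\max(0, (MS_b - MS_w)/n_0)$. The reported
percentage is the within share of total variance,
$100\,\sigma^2_w/(\sigma^2_w + \sigma^2_b)$. For the track-count sweep
the within term enters as the variance of the *estimated tumor mean*,
$MS_w/n_0$ — the quantity that actually improves as tracks accumulate;
the raw per-reading share, whose expectation does not depend on the
number of tracks, is available via `scale = "reading"`. With the mean
scale the within share falls steeply from one to three tracks and is
nearly flat beyond five — the basis for the five-to-six-track
recommendation.

*Which placement strategy is most accurate?* For each tumor the HP5
estimate of the area method is paired with the electrode estimate, and
a two-factor (tumor × method) decomposition reports the share of
variance attributable to disagreement between methods,
$100\,\sigma^2_{method}/(\sigma^2_{method} + \sigma^2_{tumor})$.
Negative moment estimates are truncated at zero, a 0/0 share is
reported as a degenerate 0, and both statistics are verified exactly
against hand-computed sums of squares. On replicate synthetic cohorts
the narrow radial fan shows the largest between-methods share, the
uniform layout the smallest, and widening the radial arc to the full
circle both lowers the between-methods share and raises the
within-tumor share — the expected effect of enlarging the effective
sampling area.

A normality summary (skewness, excess kurtosis, Shapiro–Wilk) of the
residuals from tumor means is provided as an advisory check on the
ANOVA assumptions; it never blocks an analysis.

## Radiation response

Radiosensitivity follows the linear-quadratic model scaled by the
oxygen modification factor

$$\mathrm{OMF}(pO_2) = \frac{1}{\mathrm{OER}_m}\,
  \frac{\mathrm{OER}_m\,pO_2 + K_m}{pO_2 + K_m}, \qquad
  S = \exp\left[-\alpha\,(\mathrm{OMF}\,D) - \beta\,(\mathrm{OMF}\,D)^2\right],$$

with $\alpha = 0.3\ \mathrm{Gy^{-1}}$, $\beta = 0.03\ \mathrm{Gy^{-2}}$
(48% survival at 2 Gy when $\mathrm{OMF} = 1$), $\mathrm{OER}_m = 3$
and $K_m = 3$ mm Hg, and a single enhancement ratio for both LQ terms.
Heterogeneous populations average survival over compartments with unit
weights. Six oxygenation scenarios are evaluated from one solved field:
uniform 60, 0 and 5 mm Hg; a binary classification at 5 mm Hg with the
classes represented at 5 and 60 mm Hg (the model's own moderate-hypoxia
and normoxia levels — the classification defines a cut, not class
representatives, so these are taken from the uniform cases); a 20-bin,
5-mm-Hg-wide histogram represented at bin centres (midpoint rule;
left-edge available); and the full per-cell map. The relative field is
mapped to mm Hg by assigning the field maximum `pO2_max` (default
100 mm Hg, the span the 20 × 5 mm Hg histogram implies).

## Synthetic vascular maps

Real co-registered mask sets are rarely shareable, so the package
generates them: a connected blob- or ellipse-shaped tumor mask covering
at least a quarter of the grid; single-cell vessel cross-sections
(uniformly scattered, or placed sequentially with lognormal
nearest-neighbour spacing, median 0.25 mm by default — the order of
intervascular distances reported for xenograft capillary networks); a
simple random perfused subset (default 60% of vessels, giving a
perfused vascular area fraction near 0.5%); and a *reference hypoxia
mask* marking tumor cells farther than a diffusion-limit distance from
the nearest perfused vessel, a geometric proxy for nitroimidazole
marker binding. Cohorts sweep the vessel count (default 24–80) to
create genuine between-tumor variance. Everything is bit-reproducible
from the seed, and the distance to an empty perfused set is infinite by
convention, so an unperfused tumor is entirely reference-hypoxic.

The default diffusion limit (0.15 mm) is the textbook order of an
oxygen diffusion length, but the transport model's HP5 region
corresponds to a *larger* distance (the relative threshold cuts the
field where it has decayed to 5% of its maximum). For validation
studies the two definitions must describe the same compartment:
`match_diffusion_limit()` calibrates the distance threshold on one
held-out solved domain by equating the reference area fraction with the
simulated hypoxic area fraction (a distance-quantile match, typically
0.38–0.47 mm at HP5 under default conditions). Calibrating on held-out
data and validating on fresh cohorts keeps the comparison honest; with
the matched limit, pixelwise agreement between simulated HP5 and the
geometric reference averages in the mid-80% range across cohorts.

What the generator does *not* emulate: acute (perfusion-fluctuation)
hypoxia, vessel cross-sections larger than one cell, anisotropic or
branching vascular architecture, necrotic regions, and marker-binding
chemistry beyond the distance proxy. Passing validation on these
synthetic cohorts therefore demonstrates internal consistency of the
method chain — transport, thresholding, sampling, statistics — not
fidelity to any particular histology.

## Problem sizes and determinism

The test suite and the acceptance script run the full chain on the
default 100 × 100 grid: 20 (tests) or 10 (script) replicate cohorts of
8 tumors, each solved to stationarity, sampled under all strategies and
decomposed; solver oracles run on 24–50-cell grids where exactness, not
scale, is the point. A single master seed derives every stream
(cohort synthesis, track placement, noise) through a deterministic
hash, and repeated runs of `run_experiment()` with one configuration
produce byte-identical CSV outputs (numeric columns rounded to 10
significant digits before writing).

## Known limitations

* The model is two-dimensional and chronic-only; perfusion is frozen at
  its snapshot, so acute hypoxia and reoxygenation kinetics are out of
  scope.
* Absolute oxygen tensions are not predicted; the K→mm Hg mapping for
  the radiation module is a relative rescaling, and `pO2_max` is a
  stated convention rather than a calibrated quantity.
* With the relative mapping, the survival curve of the full
  heterogeneous map tracks the anoxic curve qualitatively (it lies at
  or slightly below it when most tissue is severely hypoxic, far above
  the normoxic curve) but not within a tight log tolerance: sub-5-mm-Hg
  mass sits anywhere in (0, 5] where the OMF still varies from 1/3 to
  3/4, so near-coincidence with anoxia to within 15% of log-survival
  is *not* asserted by the tests.
* The ANOVA estimators are method-of-moments with truncation at zero —
  reproducible and exactly checkable, but not REML, and no inference
  (confidence intervals, tests) is attached to the variance shares.
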