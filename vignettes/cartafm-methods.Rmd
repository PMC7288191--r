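---
title: "Methods: AFM roughness, Hertz indentation and dehydration modelling in cartafm"
author: "cartafm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AFM roughness, Hertz indentation and dehydration modelling in cartafm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartafm)
```

# The measurement problem

Osteoarthritic degeneration changes the articular cartilage surface at the
submicron scale long before it is visible radiographically. Atomic force
microscopy (AFM) sees both sides of this process: scanned height maps
quantify surface texture, and force-spectroscopy (indentation) curves on the
same instrument quantify the local elastic response. `cartafm` implements
the full analysis chain for such studies — surface roughness parameters and
wear staging from height maps, depth-resolved Young's modulus from force
curves, and the power-law drying model used to decide when a freshly
excised specimen is stable enough to measure — together with seeded
generators that produce all three kinds of raw data with known ground
truth, so every stage of the chain is testable without instrument data.

# Roughness parameters and wear staging

Height maps are leveled by removing the least-squares plane (first order
only; measurement areas are chosen free of waviness, and higher-order
flattening would bias the amplitude parameters). Profiles are the grid rows
— the fast-scan direction of a raster AFM — and the parameters are
classical profile metrology quantities, all in nm:

* `Ra`, the arithmetic average of absolute deviations from the profile
  mean, `mean(|y - mean(y)|)`;
* `Rp`, the maximum peak height above the profile mean;
* `S`, the mean spacing between consecutive local peaks;
* `Sa`, the areal analogue of `Ra` over the whole grid.

The mean line for `Ra`/`Rp` is the plain profile mean after leveling, not a
per-profile refit — the simplest consistent definition. A local peak is a
sample strictly greater than both immediate neighbours; a plateau collapses
to its first sample, which makes `S` deterministic without a smoothing
step. An optional height-discrimination band (`min_prominence`) can ignore
peaks that do not rise a given amount above the mean line; it defaults to
off because the synthetic surfaces are smooth at the pixel scale, and real
pipelines that need it can turn it on per call.

Wear staging uses the observation that worn surfaces occupy the `Ra` range
24.6–61.2 nm at the 9×9 µm² scan area while healthy surfaces sit well above
it. The range is partitioned into three equal-width subranges of 12.2 nm,
giving interior boundaries at exactly 36.8 and 49.0 nm: `small` wear in
(49.0, 61.2], `medium` in (36.8, 49.0], `heavy` in [24.6, 36.8], `healthy`
above 61.2 and `out_of_range` below 24.6. Values on a boundary are
assigned to the more-worn side (the published inequalities are strict, so
a deterministic tie rule is needed; closing the top of the range keeps
61.2 nm a wear stage rather than healthy). The alternative range reading
"25.0–61.0" that appears alongside the tripartition is not used: only the
24.6/36.8/49.0/61.2 boundaries reproduce the printed stage limits.

Lacunae — the chondrocyte cavities that appear as elliptical depressions,
roughly 500 nm deep on worn surfaces and over 2 µm on healthy ones — are
detected as 8-connected regions of pixels deeper than a threshold below
the median surface (connected-component labelling via `EBImage`). The
median is used as the reference because lacunae themselves drag the mean
down on small maps.

# The Hertz indentation model

A force curve records cantilever deflection `Zdefl` against vertical stage
position `Zpos` (both nm). After contact, the tip penetrates by

$$h = Z_{pos} - Z_{defl},$$

and for a spherical tip of radius $R$ on an elastic half-space the Hertz
model gives $F = \tfrac{4}{3}\,\frac{E}{1-V^2}\,\sqrt{R}\,h^{3/2}$ with
$F = k\,Z_{defl}$. Solving for the modulus,

$$E(h) = \frac{3\,(1-V^2)\,k\,Z_{defl}}{4\,\sqrt{R}\,h^{3/2}},$$

evaluated internally in SI units and returned in MPa. The defaults are the
constants of a CSC38 silicon probe on cartilage: $V = 0.5$
(incompressible), $k = 0.08$ N/m, $R = 30$ nm. Published typesettings of
this relation sometimes show a 2/3 exponent on the penetration term; that
form cannot yield pressure units, and the package uses the dimensionally
consistent Hertz sphere form throughout (a worked check: `Zdefl` = 10 nm at
`h` = 100 nm gives 0.0822 MPa).

Pointwise `E(h)` diverges as $h^{-3/2}$ at contact, so depths below
`h_min` (default 10 nm, configurable) are excluded. This cutoff also sets
where the profile's "surface modulus" is read: `E_surface` is the modulus
at the smallest retained depth, and `E_max` the profile maximum with its
depth. For healthy cartilage, where `E(h)` declines monotonically, the two
coincide; worn surfaces show an interior maximum.

## Contact-point detection

The detector estimates the baseline mean and noise sd from the leading 20%
of samples and reports the first index whose deflection exceeds the
baseline by 3 sd and stays above it for 3 consecutive samples. It also
reports a `touch` index — the last sample still within one sd of the
baseline before that crossing — which is where stage position is
re-referenced for depth computation; deflection is re-zeroed to the
baseline mean rather than to a single noisy sample. On a noiseless curve
the crossing is the first nonzero deflection and the touch index is exact,
making the generator→analysis round trip exact to machine precision.

Pointwise Hertz extraction is intrinsically contact-limited at shallow
depth: a one-sample (≈2 nm) contact error rescales `E` at `h` = 12 nm by
$(12/14)^{3/2} \approx 0.77$ while leaving mid-profile values nearly
untouched. This is why replicate indentations (three per site in the
reference protocol) are averaged on a common depth grid (linear
interpolation over the overlap of the replicate ranges), why the median
over the profile is the robust quantity under noise, and why surface-
modulus values carry more uncertainty than maximum or deep values.

# The dehydration model

Excised specimens are saturated with fluid that interferes with both
imaging and indentation; they are measured after partial drying. The mass
follows

$$m(t) = m_0\,(1 + t)^b, \qquad t \text{ in hours},$$

with $b < 0$. The reported exponent is a repeating decimal whose notation
is ambiguous; the package reads it as $b = -0.\overline{14} = -14/99$,
because that value loses 30% of the initial mass by 12 h — the
experimentally determined stabilization point — whereas the alternative
reading $-0.1\overline{4} = -13/90$ loses 31%. Both are available from
`dehydration_b()`. Fitting is linear least squares in log space,
$\log m = \log m_0 + b \log(1+t)$, which is deterministic and exact on
noiseless model data; `fit_power_law()` returns a classed model object
with the usual `coef`/`predict`/`residuals`/`summary`/`plot`/`simulate`
methods. The inverse `time_to_mass_fraction(f, b)` returns
$t = f^{1/b} - 1$.

# What the generators emulate

**Surfaces.** The base texture is white noise smoothed by a Gaussian
kernel (circular FFT convolution) whose sigma is half the requested
correlation length, so the autocorrelation falls to 1/e at that length;
the zero-mean texture is then rescaled so the grand mean of row `Ra`
equals the target exactly (row `Ra` is homogeneous of degree one, so one
rescaling suffices). Lacunae are subtracted as smooth quartic depressions
$d\,(1-r^2)^2$ inside their ellipse — continuous with continuous slope at
the rim, so leveling and peak detection stay well-posed — and the tilt
plane is added last. Real cartilage topography differs in ways the
generator does not model: collagen-fiber texture is anisotropic and
fibrous (50–350 nm diameters), height distributions are skewed by
protrusions, and `Rp`/`Ra` and `S`/`Ra` ratios of Gaussian random fields
are smaller than those of real surfaces. Passing tests therefore validate
the metrology chain, not the realism of any particular ratio between
parameters.

**Force curves.** On a uniform depth grid the deflection is the exact
Hertz inverse of the prescribed modulus profile; `Zpos = h + Zdefl`;
baseline samples and the exact contact sample are prepended; Gaussian
noise (default off) is added to the deflection only, the stage position
being treated as exactly commanded, which matches AFM practice. Defaults —
200 nm maximum depth, 100 contact samples, 50 baseline samples — reflect
typical soft-tissue force spectroscopy, where indentations run to hundreds
of nanometres. Adhesion, viscoelasticity, finite sample thickness and tip
shape imperfections are deliberately out of scope: the generator produces
data for which the Hertz analysis is exactly correct, which is what makes
round-trip testing meaningful.

**Drying series.** Multiplicative Gaussian noise on the power-law mass,
`m_i = m0 (1+t_i)^b (1 + eps_i)` — the natural noise model for a balance
reading proportional error.

All generators take an explicit integer seed and leave the caller's RNG
state untouched.

# The study pipeline

`run_roughness_study()` emulates the reference design: 25 healthy and 75
worn specimens, each measured at 5 points for three scan areas (3×3, 9×9,
18×18 µm²), giving 375 and 1125 roughness records. Measurement points are
realized as non-overlapping sub-windows placed by seeded uniform sampling
over a disjoint tiling of the grid (placement cannot deadlock and is
reproducible). Group summaries (mean, n−1 sd, min, max), percent changes
of the healthy mean against the worn extreme, and per-specimen wear stages
from the mean `Ra` at the 9×9 staging area complete the report. Grid sizes
default to 96×96 pixels per map with 32-pixel sub-windows — small enough
that the full 100-specimen, 3-area study runs in seconds, large enough
that each window holds many correlation lengths. Note that `Ra` evaluated
on a 32-pixel window is systematically below the full-map value (shorter
evaluation lengths exclude low-frequency roughness, a standard metrology
effect); group contrasts are unaffected because the attenuation is common
to both groups.

`run_indentation_study()` indents one site per wear stage and layer
(1 = surface, 2–3 = subsurface cross-sections exposed by sectioning) in
three replicate curves from piecewise-linear ground-truth `E(h)` profiles:
the healthy surface declines 1.7 → 0.5 MPa; worn surfaces rise from their
surface value (1.14, 1.02, 0.82 MPa by stage) to an interior maximum
(≈1.3, 1.2, 1.2 MPa) before declining; cross-sections decline
monotonically at every stage. Replicates are averaged and summarized as
surface/maximum/deep modulus per site.

Reports are written with fixed column order and 4-significant-digit
floats, so identical configurations produce byte-identical files.

# Numerical choices and edge cases

* Leveling a constant map returns the zero map without error; leveling is
  idempotent.
* `S` is undefined (an error, not NA) on profiles with fewer than two
  local peaks; the pipeline records NA for windows where no row has two
  peaks.
* A single-observation group summarizes with sd 0 by convention.
* `compute_indentation_depth` treats depths more negative than a small
  tolerance as a hard error (a misplaced contact point), while depths
  within the tolerance — noise around the contact — are clamped to zero;
  the profile extractor widens the tolerance to a few baseline sds on
  noisy curves.
* Per-specimen seeds are derived from the master seed by a fixed integer
  hash kept below 2^31, so studies are reproducible element-wise, not just
  as a whole.

# Limitations

The package analyzes approach curves only (no adhesion or retraction
modelling), fits no finite-thickness or tip-shape corrections, and its
wear staging applies to the 9×9 µm² scan area on which the stage
boundaries were defined. The synthetic cohort reproduces the *design* of
the reference study (group sizes, measurement counts, roughness targets),
not patient-level variability; statistical hypothesis testing across
groups is out of scope.
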