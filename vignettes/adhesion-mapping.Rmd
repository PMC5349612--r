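---
title: "Mapping rolling-cell adhesion: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping rolling-cell adhesion: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollmap)
```

## The measurement problem

A cell rolling on an adhesive surface under shear flow touches the substrate
along a narrow band of its surface — the contact circumference. Adhesive
strength along that band is what controls rolling behaviour, but a centroid
track alone cannot resolve it: the same position trace is compatible with
many different contact histories, and every transient detachment shifts the
cell forward without corresponding rotation, scrambling the relationship
between position and surface coordinate.

`rollmap` reconstructs the rotation angle itself. Intracellular scatterers
visible in dark-field imaging co-rotate with the cell; their cell-frame
trajectories encode the rotation, and the rotation encodes which surface
point is in contact at every moment. Two derived quantities carry the
science:

* the **dwell time per unit angle**, $\tau(\theta) = 1/\omega(\theta)$
  (s/rad) — the longer the cell lingers while a given patch of its surface
  is in contact, the more adhesive that patch;
* the **traction metric** $r\,d\theta/dx$ — exactly 1 for rolling without
  slipping ($v = r\omega$), and well below 1 (≈0.3 by default in the
  simulator, threshold 0.5 in the classifier) for a cell convected by the
  flow while detached.

The fluorescent adhesion footprint is the molecular counterpart: surfaces
carrying DNA tension sensors that rupture digitally above ~12 pN record
every above-threshold adhesion event as a fluorescent mark, so a rolling
cell writes its adhesion map onto the substrate with period $\pi d$.

## The rotation model and its estimators

A scatterer at radial distance $R$ from the rotation axis projects to
cell-frame coordinate $x_{cm} = R\cos(\theta + \phi)$. The analysis chain
is:

1. **$R$ estimation.** The default is the maximal excursion $\max |x_{cm}|$,
   which is exact for noise-free data but inherits the largest positive
   noise excursion. The `percentile` alternative takes the 99th percentile
   of the lightly smoothed $|x_{cm}|$ (moving average, window 5), trading a
   small attenuation for a several-fold reduction of the noise bias; it is
   the pipeline default. A cosine-fit amplitude estimator exists for
   constant-$\omega$ traces.

2. **Unfolding.** $\alpha = \arccos(x_{cm}/R) \in [0, \pi]$ is two-to-one
   per cycle. Turning points are found by alternating-extremum extraction:
   a running extremum of $\alpha$ is committed as a turning point only when
   the trace has retreated from it by more than 0.6 rad. This retreat
   threshold is the hysteresis guard against the noise amplification of
   arccos near 0 and $\pi$ (where $d\alpha/dx$ diverges); it is deliberately
   much larger than any noise excursion and much smaller than the $\pi$
   swing of a genuine turning, and — unlike a fixed band around 0 and $\pi$
   — it still fires when an overestimated $R$ keeps $\alpha$ short of the
   extremes or when fast rotation steps across a narrow band between
   samples. Each committed turning is refined to its sub-sample apex by
   local tent interpolation, and endpoint extrema (a trace starting or
   ending mid-ascent) are discarded. Samples with $|x_{cm}|/R$ up to 1.1
   are clamped and flagged; beyond that they are dropped as likely
   mislinks.

3. **Parity.** Intervals between turnings alternate between $\theta = \alpha$
   and $\theta = 2\pi - \alpha$; the global parity is fixed by the sign
   convention that cumulative $\theta$ increases along the flow (+x). A
   reverse-rolling trace is unfolded with the opposite parity
   automatically.

4. **Merging.** Feature points measure the same rotation up to constant
   phase offsets. Offsets are removed by circular means against the longest
   trace; per-frame merging uses inverse-variance weights
   $\sin^2\theta_{rel} + 0.02$, since the arccos error variance scales as
   $1/\sin^2\alpha$. Traces whose residual circular deviation exceeds
   $\pi/4$ are excluded and reported. Unfolding happens per feature point,
   before merging.

5. **Circumference.** During traction $\theta = x/r + c$, so the
   least-squares slope of $\theta$ against $x$ over rolling-labelled
   samples gives $d = 2/\mathrm{slope}$. Because every detachment advances
   $x$ without advancing $\theta$, each contiguous rolling segment has its
   own intercept; the fit centers each segment separately before pooling,
   otherwise a single detachment biases the pooled slope by several
   percent. At least 4 rolling cycles are required.

On noise-free synthetic movies this chain recovers cumulative $\theta$ with
RMS below 0.035 rad (2°) and the diameter within 2%, which the test suite
asserts end-to-end.

## Dwell maps and periodicity

$\tau = 1/\omega$ is computed on rolling-labelled samples only, with an
angular-velocity floor (1% of the median rolling $\omega$) that excludes
stall samples whose dwell would be unbounded. Dwell samples are resampled
onto a uniform cumulative-$\theta$ grid (default 100 bins per 2$\pi$,
≈3.6°/bin — comfortably above the ~2° angular noise). Grid points whose
bracketing samples are more than 3 grid steps apart (detachment gaps) are
left `NA` rather than interpolated: the registration of $\theta$ with the
cell surface survives a detachment, but the dwell inside the gap is simply
unobserved, and interpolating across it dilutes the periodicity it is the
method's point to preserve.

The autocorrelation estimator is mean-subtracted and normalized per lag by
the number of available pairs (`NA`s handled pairwise), so a strictly
periodic signal keeps peaks near 1 at every multiple of its period; the
long-lag variance that a 1/N-biased estimator would suppress is controlled
instead by capping the maximum lag well below the series length. Peaks are
local maxima within ±0.2$\pi$ of the candidate lags $2n\pi$.

The characteristic patch size is read from the full width at half maximum
of the zero-lag autocorrelation peak. For a periodic top-hat patch of width
$w$ and period $P$ the mean-subtracted autocorrelation has
$\mathrm{FWHM} = w(1 - w/P)$, so the reported fraction inverts that
relation, $(1 - \sqrt{1 - 4\,\mathrm{FWHM}/P})/2$, which returns exactly
$w/P$ for top-hat patches and reduces to $\mathrm{FWHM}/P$ for narrow
peaks. The inversion grows ill-conditioned as $\mathrm{FWHM}/P \to 1/4$
(patches near half the circumference); fractions at or above 0.5 are
flagged rather than extrapolated.

The translation-only control ("dwell versus position") has no unique
definition from centroid data; this package uses
$\tau_x(x) = \hat r / v(x)$ with the population-mean radius, sampled
uniformly in $x$ *including* detachment spans. Diameter spread and, above
all, detachment slip (position advances ~0.7 of the convection distance per
event relative to rotation) destroy the $x$-periodicity that the
$\theta$-axis analysis retains — the core argument for rotation tracking,
and the package's population-level acceptance property.

## Footprint image pipeline

Flat-field correction follows
$I_{corrected} = (I_0 - I_{bg})/I_{illumination}$, with the illumination
profile estimated as the normalized pixelwise mean of background-subtracted
tiles (the sparse signal averages out; hundreds of tiles make it accurate
to ~2% RMS). With only a dozen tiles, the pipeline smooths the estimate
(default 16 px) and floors it (default 0.25) so the correction cannot
amplify the sparse-spot residue; both knobs are exposed in the pipeline
config. Stitching estimates integer pixel offsets by maximizing the
normalized correlation of overlap strips over a ±5 px search window and
joins tiles without blending (the later tile owns the seam); a correlation
below 0.5 falls back to the nominal offset with a flag. Track bands are
isolated from the transverse intensity profile of the smoothed mosaic;
bands that touch are dropped, mirroring the practice of analysing only
isolated tracks.

Periodicity comes from two independent routes that must agree: the 2D
zero-normalized cross-correlation of one repeating unit against the whole
track (period = median spacing of correlation maxima along $x$) and the 1D
autocorrelation of the transversely summed track (lag axis normalized by
$\pi d$). The contact width is the extent of the transverse mean profile
above background plus `max(3 × noise SD, half the peak height)`: the
half-maximum floor places the crossing at the true edge of a PSF-blurred
top-hat band regardless of blur and noise level, where a pure
3-SD-above-background crossing would inflate the width by roughly two PSF
widths on clean data. Contact area assumes a circular contact patch,
$A = \pi(w/2)^2$, and the surface fraction divides by the sphere surface
$\pi d^2$.

## What the simulators emulate — and what they do not

The movie generator renders a sphere (default 14.1 um) rolling along +x at
30 fps and 0.53 um/px (25x on a 16-um-pixel EMCCD), as a dim disk with a
brighter rim plus Gaussian scatterers that follow
$x = R\cos(\theta+\phi)$; rotation integrates
$d\theta/dt = 1/\tau(\theta)$ through the ground-truth dwell profile
(baseline 0.3 s/rad in the study conditions, i.e. mean rolling speeds of a
few um/s), and detachment intervals convect the cell at 5x its rolling
speed with $r\,d\theta/dx = 0.3$. The footprint generator draws rupture
events from an inhomogeneous Poisson process whose surface density is
proportional to the local dwell (bright where adhesion is strong), renders
them at the ~250 nm optical resolution on a 0.16 um/px (100x) grid inside
a 5.7-um track band, applies a vignette fixed to the camera frame, and
splits the image into overlapping tiles. The population generator draws 30
cells with diameters N(14.1, 1.0) um, 1–3 additive top-hat patches (width
$\pi/6$–$5\pi/6$, dwell multiplier 2–8) and Poisson(0.6/cycle) detachments
of 1–2.5 s. The microvilli model places 730 villi area-uniformly on the
sphere (17 receptors each) and counts tethers in 20° angular bins as each
villus enters a contact band of width 5.7 um — after placement the geometry
is deterministic, so per-bin counts repeat exactly every cycle.

Deliberately not modelled: cell deformation and catch-bond kinetics (the
dwell profile is a fixed property of the surface), depth-dependent
scatterer contrast (available but off by default), out-of-focus blur,
rotation-plane drift, membrane slings, and any DNA mechanics beyond the
digital rupture threshold. Passing tests therefore demonstrate that the
*estimators* recover known ground truth under realistic imaging geometry
and noise — not that real cells obey the generative model. Two practical
limitations found while validating on synthetic movies carry over to real
data: scatterers whose projections approach the bright cell rim acquire a
centroid bias, and scatterers closer than ~2 um transversely merge at
crossings and fragment their trajectories; usable fiducials should be
separable and away from the projected rim, which is also how they are
selected by eye in practice.

## Numerical choices and degenerate inputs

* Angular-velocity and velocity derivatives are central differences with
  optional moving-average smoothing (pipeline default 5 frames); endpoints
  are one-sided.
* The traction classifier fits $\theta$-vs-$x$ slopes in 9-sample sliding
  windows; windows whose $x$-range is below 0.2 um (stalled cell) are
  labelled ambiguous rather than divided by zero. Label thresholds: rolling
  ≥ 0.75, detached ≤ 0.5.
* Spot detection defaults to a maximally-stable-extremal-regions analysis
  (threshold sweep over the nested component tree, stability = relative
  area variation ≤ 0.35, area 3–120 px, contrast ≥ 6 MAD above the frame
  median), with centroids refined by background-subtracted intensity
  weighting; a Laplacian-of-Gaussian detector sits behind the same
  contract because stability parameters are a free choice.
* Cell segmentation clips the top 2% of intensities before Otsu so the
  bright scatterers cannot capture the threshold; components under 50 px
  are discarded. Linking is greedy nearest-neighbour (gate = one cell
  radius per frame for cells; 2.5 um with transverse displacements
  inflated 3x for spots, since a spot's y is constant during on-axis
  rolling), deterministic tie-break toward smaller y.
* Empty frames segment to zero regions; a movie with no cells produces an
  empty QC table, not an error; cells failing the 4-cycle criterion are
  QC-reported with the reason.
* All generators are seeded and bit-reproducible; every numeric pipeline
  output carries a hash of the analysis config.

Test and acceptance problem sizes were chosen to exercise every stage at
realistic scale while staying light: single-cell movies of 4.5–5.5 cycles
(600–900 frames), footprint tracks of 4–5 periods (~10–15 tiles),
populations of 30 cells at the dynamics level, and 100-seed Monte-Carlo
loops for the statistical properties.

## Wall shear stress

The flow-channel calculator uses the infinite-parallel-plate law
$\tau_w = 6\mu Q/(w_0 h_0^2)$, the standard approximation for thin
rectangular channels (an 80 um x 2 mm cross-section has aspect ratio 25:1,
where the finite-width correction is a few percent). Viscosity defaults to
water at room temperature (1.0 mPa s) and is exposed, since buffer
viscosity and temperature shift $\tau_w$ proportionally: at 100 uL/hr the
default channel gives 0.013 Pa.
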