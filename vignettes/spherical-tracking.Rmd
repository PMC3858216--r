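---
title: "Tracking fluorescent foci on spherical cells: methods and design notes"
author: "orbitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking fluorescent foci on spherical cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitrack)
```

## The measurement problem

During sporulation, some bacteria round up into near-spherical spores of
roughly 1.5 µm diameter while envelope protein complexes condense into a
handful of bright fluorescent clusters that are transported around the spore
surface. A single-plane time-lapse movie shows these clusters as
diffraction-limited spots moving inside the projected disk of the cell. Two
properties make the analysis non-trivial:

* the motion happens on a **sphere**, so the planar (Euclidean) distance
  between two spot positions systematically underestimates the distance
  actually travelled along the surface;
* only one focal plane is imaged, so the out-of-plane coordinate of a spot
  must be reconstructed from its in-plane position.

orbitrack implements the full chain — cell segmentation with subpixel
contours, spot detection by Gaussian fitting, projection into spherical
coordinates, great-circle trajectory linking, and MSD-based motion
decomposition — together with a synthetic movie generator that renders
ground-truth surface trajectories into realistic noisy image stacks, so that
every stage can be validated against known parameters without any external
data.

## Coordinate system and orthodromic distances

Each segmented cell provides a center, a sphere radius $p$ (the mean
center-to-contour distance, in µm) and a major-axis direction used as the
angular reference. A detection at planar distance $r$ from the center and
angle $\theta$ (counterclockwise from the major axis) is lifted onto the
sphere with the elevation angle

$$\varphi = \arccos(r / p), \qquad \varphi \in [0, \pi/2],$$

so a focus on the projected rim has $\varphi = 0$ and a focus over the
center has $\varphi = \pi/2$. The unit position vector is
$n = (\cos\varphi\cos\theta,\ \cos\varphi\sin\theta,\ \sin\varphi)$ and the
surface (orthodromic) distance between two positions is the great-circle
arc

$$d = p \arccos\big(\cos\theta_1\cos\varphi_1\cos\theta_2\cos\varphi_2 +
 \sin\theta_1\cos\varphi_1\sin\theta_2\cos\varphi_2 +
 \sin\varphi_1\sin\varphi_2\big).$$

The package carries three algebraically equivalent routes to this quantity
(the trigonometric formula above, the dot product of the 3D unit vectors,
and the chord-then-arc lift from planar coordinates) and its test suite
verifies their agreement to $10^{-9}$ on $10^4$ random pairs.

**Hemisphere ambiguity.** Because $\varphi \ge 0$, a single imaging plane
cannot distinguish a focus above the focal plane from one below it; all
detections are placed on one hemisphere. Pairs of positions that truly lie
on opposite hemispheres therefore get an underestimated distance. This is a
property of the coordinate reconstruction itself, and it is deliberately
*documented rather than corrected*: the reconstruction matches what a
single-plane acquisition can know. Its main consequence is a downward bias
of the MSD at large lags (quantified below), which motivates the small-arc
fitting rule.

## Motion decomposition

For each track, instantaneous speeds (orthodromic step over frame
interval), the cumulated path and the distance from origin are computed; an
ensemble MSD is built per frame lag by time-averaging over all observation
pairs within each track and pair-count weighting across tracks. The
ensemble curve is fitted without intercept to

$$\mathrm{MSD}(t) = 4 D t + v^2 t^2,$$

by nonnegative weighted least squares on the basis $\{4t,\ t^2\}$, which
separates the apparent surface diffusion coefficient $D$ from the mean
transport velocity $v$. The log–log slope $\alpha$ of the curve and the
share of the quadratic term classify the motion: arrested (MSD below a
noise floor of 0.01 µm², i.e. 100 nm RMS), subdiffusive ($\alpha < 0.9$),
directed ($\alpha > 1.2$ and quadratic share ≥ 0.5), else diffusive.

**Small-arc fitting rule.** The quadratic relation is the planar small-arc
expansion of motion on a sphere. At arcs approaching the sphere scale two
effects depress the measured MSD below $4Dt + v^2t^2$: great-circle
distances saturate at $\pi p$, and the hemisphere ambiguity folds
cross-hemisphere pairs. For the geometry studied here ($p = 0.75$ µm,
$v \approx 0.12$ µm/min, 0.5 min frames) these effects reach tens of
percent at half the available lag range, and fitting over that range biases
$v$ down by about a third even on ground-truth trajectories. The $(v, D)$
fit is therefore restricted to lags whose RMS angular displacement
$\sqrt{\mathrm{MSD}}/p$ stays below 0.5 rad — the regime where the
small-angle expansion is accurate to a few percent — while the shape
statistics ($\alpha$, quadratic share), which describe the observable curve
rather than the model, keep the conventional first-half lag range. With
this rule the pipeline recovers $v$ to within about 0.02–0.04 µm/min of the
generative value under the hemisphere folding it cannot remove.

## Image processing choices

* **Segmentation.** Cells are located by a global Otsu threshold, but the
  subpixel contour is extracted by marching squares at the *half-height
  level* between each cell's interior plateau and its local background.
  This pins the contour to the midpoint of the PSF-blurred edge regardless
  of where the global threshold falls, which matters because the fitted
  radius $p$ scales every distance downstream. A grayscale opening first
  removes bright foci (including the ridges they leave in temporal
  projections by dwelling near the projected rim), and a 1 px Gaussian
  presmoothing suppresses shot-noise raggedness; its curvature-induced
  inward bias is about $\sigma^2/2r < 0.1$ px here. On clean disks the
  fitted radius is accurate to ~0.3 px; on noisy renders to ~0.2 px.
* **Eccentricity gates.** Shape gating uses the standard moments
  eccentricity $e = \sqrt{1 - \lambda_2/\lambda_1}$, computed from exact
  polygon moments of the contour. For nearly round shapes this metric is
  sqrt-amplified: a relative radius modulation $\varepsilon$ gives
  $e \approx \sqrt{8\varepsilon}$, so 0.1 px of boundary noise on a 7.5 px
  cell already produces $e \approx 0.3$. The degenerate-axis cut (0.45) and
  the sphere-fit bound (0.6) correspond to minor/major axis ratios of about
  0.9 and 0.8; visibly elongated (2:1) cells have $e = 0.87$ and are still
  rejected. For spheres the major axis is undefined: the axis is reported
  as the image x-axis with a degenerate flag, making $\theta$ arbitrary up
  to a rotation — all distances are rotation-invariant, so only the
  $\theta$ labels, not any statistic, depend on it.
* **Detection.** Spot candidates come from a white top-hat transform
  (frame minus its grayscale opening) smoothed with a PSF-matched kernel:
  unlike a difference-of-Gaussians band-pass, the top-hat leaves no ridge
  response at cell rims. Local maxima above the robust background plus
  $k\sigma$ (default $k = 5$; over the ~$10^6$ pixel-frames of a movie a
  $3\sigma$ cut admits tens of false maxima while the matched-filter SNR of
  even a strongly defocused focus exceeds ~40) are merged within one PSF
  FWHM and refined by a 2D Gaussian fit in a 7×7 window with an
  intensity-weighted-centroid fallback. Fits narrower than 0.7× or wider
  than 3× the PSF are rejected (noise spikes and background blobs). RMS
  localization error on bright rendered foci is ~0.05 px.
* **Pipeline preprocessing.** `run_track` segments on the temporal
  20 %-quantile projection of the stack (moving foci drop out of a low
  quantile even when they dwell near the projected rim) and detects on the
  normalized stack minus that static projection, the standard
  static-structure subtraction of single-particle tracking.
* **Linking.** Consecutive frames are linked per cell by a globally optimal
  one-to-one assignment minimizing total orthodromic distance (exact
  branch-and-bound for the small per-cell focus counts, with a gated greedy
  fallback beyond nine), with links above `max_step` (default 3× the
  per-frame displacement at the upper observed speed of 0.3 µm/min)
  forbidden. Two safeguards keep track identities pure, which
  time-averaged MSDs depend on: *ambiguity pruning* drops a link whenever a
  rival head or candidate lies within `max_step`/4 of the chosen cost
  (close encounters cannot be disambiguated without a motion model, and a
  wrong guess scrambles identities), and *gap closing* over up to 2 frames
  bridges the resulting interruptions, including those caused by two foci
  blending below the diffraction limit — such blended detections are
  recognized by their broadened fit width (> 1.15× PSF) and discarded
  before linking.

## The synthetic generator

The generator emulates the study conditions: near-spherical cells of radius
0.75 µm on a grid, 1–2 foci per cell, 60 frames at 0.5 min intervals,
0.1 µm pixels, a 0.13 µm PSF. Motion regimes:

| preset | regime | parameters |
|---|---|---|
| WT | directed along a random great circle | $v = 0.12$ µm/min, $D = 0.012$ µm²/min |
| exoA | directed with Poisson reversals | same $v, D$; reversal rate 2 min⁻¹ |
| aglQ | arrested, residual jitter about an anchor | $D = 0.001$ µm²/min |
| blank | no foci | — |

Directed motion advances the position along a great circle at angular rate
$v/p$ with the heading parallel-transported; tangential Brownian jitter of
per-axis variance $2D\,\mathrm{d}t$ is added and the position reprojected
(valid for steps ≪ $p$; the per-step arc MSD matches $4D\,\mathrm{d}t$
within a few percent against an independent Monte-Carlo oracle). Arrested
foci jitter independently *about a fixed anchor*, which produces the
plateaued (subdiffusive-looking) MSD seen for motor-dead mutants, rather
than a free diffusion with small coefficient. Reversal events flip the
heading as a Poisson process.

Rendering places each focus as a 2D Gaussian at its orthographic
projection, with a photon-conserving defocus attenuation
$1/(1 + ((z - z_{\mathrm{focal}})/h)^2)$ ($h$ = 0.6 µm half-depth) — only
the intensity loss matters to a single-plane tracker, so no 3D PSF is
modelled. The cell body is a disk of diffuse reporter fluorescence
(60 counts over a 100-count background) with a PSF-blurred edge — it is
this diffuse signal that makes cells segmentable in the fluorescence
channel, as in the real movies. Noise is Poisson on the full expected
signal plus 2-count Gaussian read noise, and a ±10 % sinusoidal
illumination drift multiplies each frame (the fluctuation that
frame-by-frame background normalization inverts exactly). Pixel size, frame
interval and all of the above are configurable; none are stated by the
reference experiments, so the defaults are declared, realistic choices.

**What the generator does not emulate:** photobleaching, cell crowding and
touching cells, z-stacks, defocus PSF broadening, camera gain structure,
and any coupling between foci. Passing tests on synthetic data therefore
validate the geometry, statistics and bookkeeping of the pipeline — not its
robustness to every property of real micrographs.

## Validation summary

The test suite (all expectations computed from ground truth or independent
oracles; seeds fixed) covers, among others:

* noiseless directed kinematics exact to $10^{-9}$ (per-step arc
  $= v\,\mathrm{d}t$; cumulated arc over 59 steps = 3.54 µm);
* diffusive per-step arc MSD $= 4D\,\mathrm{d}t$ against an independent
  tangent-step Monte-Carlo oracle; ensemble MSD slope $/D = 4$ within 15 %;
* analytic MSD curves fitted to machine precision
  ($t^2 \to v = 1, D = 0$; $4t \to v = 0, D = 1$);
* frame-pair assignments equal to a brute-force enumeration oracle;
* detection recall, precision ≥ 0.95 and RMS localization ≤ 0.15 px, and
  zero identity switches, on well-separated rendered fixtures;
* regime classification ≥ 90 % correct over 20 seeded ensembles per preset;
* end-to-end recovery of $v$ within ±0.05 µm/min and $D$ within
  ±0.007 µm²/min of the generative values from rendered WT movies
  (25 foci, 60 frames), with the median instantaneous speed inside the
  0.1–0.3 µm/min band.

Problem sizes in the default suite — 25-track ensembles, 60-frame 160×160
px stacks, 20 seeds per classification regime — were chosen to match the
study conditions (ensembles of ≥ 15 trajectories) while keeping each
end-to-end run around ten seconds.

## Known limitations

* The hemisphere ambiguity is inherent to single-plane $\varphi =
  \arccos(r/p)$ reconstruction; distances for cross-hemisphere pairs are
  underestimated and $v$ retains a downward bias of roughly 0.02–0.04
  µm/min under the study conditions even after the small-arc fitting rule.
* Foci closer than the diffraction limit are merged by design
  (multi-emitter fitting is out of scope); their tracks break at the
  encounter and continue under new identifiers.
* The linker uses no motion model (no Kalman prediction), trading a few
  track breaks for guaranteed identity purity.
* `fit_sphere` assumes a rounded cell; rod-shaped (pre-sporulation) cells
  are rejected by the eccentricity gate rather than analyzed along a
  centerline.
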