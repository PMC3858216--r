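# orbitrack

Subpixel tracking and motion analysis of fluorescent protein clusters on the
surface of spherical sporulating bacteria, from single-plane time-lapse
fluorescence microscopy.

When a rod-shaped bacterium rounds into a ~1.5 µm spore, envelope transport
complexes condense into a few bright foci that rotate around the spore
surface. Quantifying that motion from a single focal plane requires more
than 2D spot tracking: positions must be lifted onto the spore sphere and
distances measured along great circles, because planar distances
systematically understate surface travel. orbitrack is aimed at
microbiologists and image analysts who need those surface-motion statistics
from TIFF time-lapse stacks — or who want to validate such a pipeline end to
end on synthetic movies with known ground truth.

## What it computes

1. **Cell geometry** — Otsu segmentation with subpixel periodic-spline
   contours extracted at the half-height of the PSF-blurred edge; sphere
   radius `p` (mean center-to-contour distance) with a circularity
   diagnostic; major-axis direction (flagged degenerate for spheres).
2. **Foci** — background-drift normalization, white top-hat spot detection,
   subpixel 2D Gaussian fits (RMS localization ~0.05 px on bright spots).
3. **Spherical trajectories** — polar coordinates `(r, θ)` about the cell
   center, elevation `φ = arccos(r/p)`, great-circle (orthodromic)
   distances

   `d = p·arccos(cosθ₁cosφ₁cosθ₂cosφ₂ + sinθ₁cosφ₁sinθ₂cosφ₂ + sinφ₁sinφ₂)`,

   and globally optimal nearest-neighbour linking with conservative
   ambiguity handling and gap closing.
4. **Motion decomposition** — instantaneous speeds, cumulated distance,
   distance from origin, ensemble time-averaged MSD, and the second-order
   fit `MSD(t) = 4Dt + v²t²` separating the transport velocity `v` from the
   apparent surface diffusion `D`, with a regime call
   (directed / diffusive / subdiffusive / arrested).
5. **Quantifications** — single-cell intensity-ratio time courses,
   lectin-stain area ratios, foci-per-cell counts, kymographs resliced
   along a cluster path.
6. **Synthetic movies** — a generator that simulates surface motion
   (directed, diffusive, arrested, directed-with-reversals) and renders it
   into noisy 16-bit TIFF stacks with defocus dimming, Poisson noise and
   illumination drift, plus ground-truth CSV tables.

## Worked example

Simulate the directed-transport condition (25 foci on 13 spherical cells,
60 frames at 0.5 min), run the full pipeline on the rendered images, and
decompose the motion:

```r
library(orbitrack)

cfg   <- pipeline_config()        # 0.1 µm/px, 0.5 min/frame, defaults
scene <- run_simulate(cfg, "WT", n_foci = 25, n_frames = 60, seed = 7)
res   <- run_track(cfg, scene$stack)
rep   <- run_analyze(cfg, res$tracks)
rep$estimate
#> MSD second-order fit (MSD = 4Dt + v^2 t^2)
#>   v      = 0.0848 um/min
#>   D      = 0.01136 um^2/min
#>   alpha  = 1.271 (log-log MSD slope)
#>   regime = directed  (n_tracks = 47)
median(rep$speeds)
#> [1] 0.2508
```

The generative parameters were `v = 0.12 µm/min` and `D = 0.012 µm²/min`:
`D` is recovered almost exactly, and `v` comes back at ~0.08–0.11 µm/min —
the residual shortfall is the documented hemisphere ambiguity of
single-plane imaging (`φ = arccos(r/p)` cannot tell above-plane from
below-plane, which shortens cross-hemisphere distances). The median
instantaneous speed of 0.25 µm/min sits inside the 0.1–0.3 µm/min band
expected for active transport at these parameters. Foci-per-cell counts on
the first frame:

```r
count_foci_per_cell(subset(res$detections, frame == 0), res$geometries)$summary
#>       mean       sd max fraction_with_foci n_cells
#> 1 1.769231 0.438529   2                  1      13
```

A thin command-line wrapper with `simulate` / `track` / `analyze`
subcommands is installed at `inst/scripts/orbitrack.R`; each stage writes
CSV/JSON/PNG outputs and a run manifest. See the vignette
(`vignettes/spherical-tracking.Rmd`) for the model, the coordinate system,
all tunable parameters and the design rationale.

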