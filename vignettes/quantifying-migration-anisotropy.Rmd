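---
title: "Quantifying migration anisotropy in spheroid invasion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying migration anisotropy in spheroid invasion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromigrate)
```

## The measurement problem

Cell-free tissue-engineering biomaterials succeed or fail by how well
autologous cells invade them. Classical 2D layer assays seed a confluent
monolayer against one face of the material and measure how deep cells get;
they yield one direction per experiment and struggle with non-planar
surfaces. Placing a centrifugation-formed cell spheroid on the material
instead gives a spatially localized, point-like cell source, so a single
cross-section captures migration along both principal directions of the
material — provided the resulting nucleus distribution can be quantified.

`spheromigrate` implements that quantification chain:

1. **Nucleus detection** — maximum projection of consecutive confocal
   planes, global or manual thresholding, 8-connected particle analysis
   with area and circularity filters (`detect_sample()`).
2. **Migration distances** — per-nucleus minimum Euclidean distance to the
   source outline (spheroid assay) or the contacted surface (layer assays),
   summarized as per-sample medians (`sample_distances()`).
3. **Local density maps** — overlapping circular ROIs on a regular lattice,
   density in cells/mm² (`build_density_grid()`).
4. **Isodensity profiles** — per lattice column, the deepest ROI at or
   above a density threshold whose next two deeper ROIs are both below it;
   the deepest perimeter point of each such ROI, joined left to right
   (`extract_profiles()`).
5. **Isodensity ellipses and R\*** — direct least-squares conic fits of the
   profiles; the corrected anisotropy ratio R\* = b / (a − P)
   (`fit_ellipse()`, `compute_R_star()`).
6. **Reference diffusion simulation** — 2D anisotropic diffusion from a
   line source, giving idealized iso-concentration profiles for
   vertical:horizontal coefficient ratios 2:1, 1:1 and 1:2
   (`solve_diffusion()`).

## Coordinate conventions and units

All geometry is in micrometres; densities are in cells/mm²
(1 mm² = 10⁶ µm²). `register_frame()` maps every sample into a common
frame: the least-squares line through the interface polyline becomes y = 0,
x runs parallel to the interface ("horizontal"), and y is depth into the
material ("vertical", y > 0). The cell-source outline ends up at y < 0,
which is how the orientation of the frame is decided. Interfaces that
deviate from their least-squares line by more than one ROI diameter trigger
a warning: the flat-interface approximations used downstream (profile
points at center + radius, flat interface band) degrade with curvature.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `roi_diameter` | 200 µm | circular ROI diameter of the density lattice |
| `roi_overlap_fraction` | 0.5 | lattice spacing = diameter × (1 − overlap) = 100 µm |
| `reference_density` | 950 cells/mm² | reference for the percentage labels |
| `density_thresholds` | 50, 95, 150, 475 | 5%, 10%, 15%, 50% of the reference |
| `band_height` | 200 µm | interface band for `band_density()` |
| `p_reference` | 745 µm | spheroid radius P subtracted from semi-major axes |
| `min_area`, `max_area` | 20, 500 µm² | particle area filter |
| `min_circularity` | 0.3 | particle roundness filter (4πA/P²) |

The published thresholds 50 and 150 cells/mm² are rounded values of 5% and
15% of 950; the printed values are used as defaults and are not regenerated
from the percentages. The original study does not print its particle-filter
cut-offs, so ours are exposed configuration, not claims about the original
analysis. The ROI size matters: too large a ROI overestimates migration
depth in barrier-like materials with shallow invasion; too small a ROI
yields noisy, fluctuating profiles. The defaults match materials with
millimetre-scale profiles.

The 50% profile is computed and exported but excluded from R\* by default
(`anisotropy_thresholds`), because near-source densities are dominated by
the cell source itself rather than by migration.

## Numerical choices

**Lattice phase.** ROI centers sit at x = x_min + j·spacing and
y = spacing·(i + 1), so the first ROI row lies fully inside the material,
where density is defined. Nuclei exactly on a ROI circle count as inside
(deterministic tie-break); a nucleus can and should count in several
overlapping ROIs.

**Threshold-ROI rule at column ends.** The "next two deeper ROIs below
threshold" condition treats ROIs beyond the grid as density 0, so the
deepest populated ROI remains selectable.

**Lateral origin.** The x that halves the area under a profile is found
exactly on the piecewise-quadratic cumulative trapezoid area; the origin is
the mean over the 5%, 10% and 15% profiles.

**Ellipse fitting.** Profiles are half-arcs; unconstrained conic fits to
half-arcs are ill-conditioned. Each profile is therefore mirrored across
y = 0 before the direct least-squares fit with ellipse constraint (stable
block formulation, with centering/scaling of the data for conditioning).
Semi-axes come from the eigendecomposition of the conic's quadratic form,
which is independent of the half- versus full-coefficient convention of
closed-form transcriptions; the classical closed-form semi-axis formula is
kept as an internal cross-check and agrees to 10⁻⁷ in the tests. The axis
whose direction lies closer to the x-axis is labeled a (lateral), the other
b (depth) — labels follow orientation, not magnitude, because
R\* = b/(a − P) requires a to be the lateral extent even when b > a.

**Particle measurement.** Components are 8-connected; perimeters are
marching-squares boundary lengths of the 0.5-level contour of each
component, and circularity 4πA/P² is clamped to [0, 1]. The automatic
binarization threshold maximizes between-class variance over all integer
gray levels (Otsu); a manual numeric threshold mirrors the original
manual setting.

**Diffusion solver.** Explicit finite differences (FTCS) on the 5 × 5 mm
square at 51 × 51 nodes, time step bounded by h²/(2(D_v + D_h)) with a 0.9
safety factor; Dirichlet 100% on the centered 19 source nodes (18 edge
elements, 1.8 mm), zero-flux elsewhere; one 432,000 s step. The higher
coefficient is the derived migration speed 1.16 × 10⁻⁶ (500 µm over 5
days), reused numerically as mm²/s — a modeling convention, not a physical
identity. Temporal error at this step size is below 0.2% of the source
concentration. Pointwise grid convergence is limited by the corner
singularity of the continuum solution at the Dirichlet/zero-flux junctions
(the source tips); convergence is therefore assessed as the RMS nodal
difference against a 4×-refined grid carrying the same physical source
length, which is ≈ 0.7% of the source concentration for all regimes.

**Comparing simulated and measured profiles.** `contour_anisotropy()`
computes depth extent over (lateral half-extent − source half-length). With
the geometric half-length (0.9 mm) the isotropic regime yields ≈ 1.3, not
1: a held line source penetrates ≈ 1.16·√(4Dt) at its center but only
≈ 0.91·√(4Dt) beyond its tips, where the source amplitude is effectively
halved. The same bias affects the experimental R\*, which is why P is
calibrated on a reference material rather than measured. The simulation
side mirrors that calibration: `contour_extents()` plus `calibrate_P()`
with reference R = 1 on the isotropic regime give an effective source
half-length (per-level values agree to < 1%), after which the isotropic
ratio is 1.00 and the regime ordering 2:1 > 1:1 > 1:2 holds at every
level.

## The synthetic generator

`generate_points()` draws nuclei by rejection sampling from
f(x, y) ∝ exp(−q), q = √((max(0, |x| − P)/s_h)² + (y/s_v)²), y ≥ 0, with
s_h = `decay_scale` and s_v = `anisotropy_true` · s_h. This emulates the
essential structure of the assay — a uniform-density plateau under the
source contact and an anisotropic exponential decay away from it — with
closed-form moments, so `anisotropy_true` is exactly the vertical:lateral
ratio the pipeline should report as R\* when P = P_true. Defaults
(n = 5,000 cells, P = 745 µm, decay scale 250 µm, 5,000 × 3,000 µm domain)
produce profile extents of one to two millimetres, the scale observed in
porous collagen scaffolds. A second generator
(`generate_points_from_field()`) samples from the diffusion solution for
cross-validation. `rasterize()` stamps additive intensity disks for testing
the image-based path.

What the generator does *not* emulate: pore-scale density fluctuations and
channel-guided cell chains, spheroid indentation into the material,
imaging artifacts (uneven illumination, out-of-focus light), and touching
nuclei resolvable only by watershed splitting. Passing the recovery tests
therefore shows the pipeline is correct for smooth density fields with
known anisotropy — not that segmentation or registration is robust to all
features of real micrographs.

## Validation problem sizes

The test suite fits 100 random noiseless ellipses (recovery to 10⁻⁶
relative), checks the threshold-ROI rule against exhaustive enumeration on
1,000 random columns, compares distances with a brute-force point–segment
oracle on 100 instances of 100 points × 20 vertices, and runs the full
pipeline on 30 synthetic samples of 5,000 cells (anisotropy 0.5/1/2 × 10
seeds): recovered mean R\* lies within 20% of the truth in each regime,
the per-seed ordering in true anisotropy is strictly monotone, and the
isotropic regime gives |R\* − 1| ≤ 0.2 in at least 8 of 10 seeds. These
sizes keep the default suite under a minute while leaving the stochastic
checks well away from their thresholds.

## Known limitations

- Curved interfaces are flattened by a rigid least-squares registration;
  strongly non-planar surfaces (sagitta beyond one ROI diameter) are
  outside the intended regime and only warned about.
- R\* is undefined when a ≤ P (barrier-like materials whose lateral
  profile extent does not exceed the source radius); it is reported as
  `NA`, not extrapolated.
- No watershed splitting of touching nuclei and no 3D segmentation; dense
  near-source regions undercount.
- Per-sample standard deviations of published group summaries cannot be
  recomputed without the original per-sample microscopy data; the package
  validates against printed group means and its own synthetic ground
  truth instead.
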