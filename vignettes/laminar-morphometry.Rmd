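---
title: "Cerebellar laminar morphometry: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebellar laminar morphometry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cereblam)
```

## The problem

The cerebellar cortex is a tightly folded three-layer sheet: the internal
granular layer against the white matter, the one-cell-thick Purkinje layer in
the middle, and the molecular layer against the pia. In gadolinium-enhanced
ex vivo MRI at ~40 µm resolution the Purkinje layer appears as a thin bright
lamina, which makes a fully laminar morphometry possible — per-lobule volume,
thickness, and surface area for each layer separately, not just for the
cortex as a whole. Two obstacles dominate:

1. **Vanished fissures.** Adjacent folial surfaces touch; the CSF gap between
   them is lost to partial volume, so the pial surface cannot be read off an
   intensity segmentation inside closed sulci.
2. **A thin, curved, inconstant lamina.** The Purkinje layer is one voxel
   thick, highly curved at folial crowns, and its contrast varies with local
   myeloarchitecture; no global threshold or mixture model isolates it.

`cereblam` implements a voxel-based pipeline that addresses both: geodesic
(Eikonal) fissure skeletonization recovers closed sulci from the distance
field itself, and a Hessian planeness filter plus an equivolume laminar model
recovers the complete Purkinje sheet from its detectable parts. Group
statistics then compare W-scored (head-size-adjusted) morphometrics between
cohorts.

Because no raw volumes ship with the package, every stage is validated
against analytic phantoms the package generates itself; this vignette
explains the models, the tunable parameters, and exactly what those phantom
validations do and do not establish.

## Stage models

### Tissue segmentation

Intensities inside the cerebellar mask are standardized by piecewise-linear
histogram matching on 11 landmarks (percentiles 1, 10, ..., 90, 99), then a
univariate Gaussian mixture with K = 4 classes (one WM, three GM — the three
cortical laminae have distinct intensities) is fitted by EM. The E-step
optionally weights responsibilities by per-voxel spatial priors; the
log-likelihood is checked to be non-decreasing at every iteration, and a
collapsed component triggers a seeded restart with perturbed means.

The WM candidate (top-mean class) contains Purkinje-layer voxels, whose
intensity is close to WM. Cleanup removes planeness-positive voxels and keeps
the largest 26-connected component. One subtlety: at cleanup time no cortex
mask exists yet, so the planeness response is computed over the whole
cerebellar mask and also fires along the WM/GM interface; subtracting it
verbatim strips the WM boundary shell (we measured Dice 0.67 against phantom
WM). `clean_wm()` therefore reclaims removed voxels still 26-connected to the
surviving WM core within two dilation steps: a detached lamina sheet stays
out, the boundary shell returns (Dice ≈ 1 on the phantom).

### Geodesic fissure extraction

A speed map `F = I * G_sigma` (masked, normalized Gaussian smoothing of the
standardized intensity, default `sigma_speed = 1.5` voxels; the printed value
carries no unit, and a `sigma_unit = "mm"` switch is exposed) drives the
Eikonal equation `F |grad D| = 1`, solved by first-order fast marching from
the WM/GM boundary. Fronts climbing the two walls of a closed sulcus collide
at the contact surface, producing a ridge of `D`.

At a collision shock the gradient of `D` is tangent to the fissure sheet (the
across-sheet component cancels), so a literal "local maximum along the
gradient" marks nothing — we measured exactly zero candidates on the
touching-fold phantom. The ridge line used instead is the principal direction
of the Hessian of the lightly smoothed distance map with the most negative
eigenvalue, i.e. the front-collision direction; `D` must be maximal against
trilinear samples one voxel either way along it. Two further gates keep the
operator specific:

* **Prominence.** A layered speed map produces shallow creases along the
  bright lamina (faster fronts racing along it collide at glancing angles) —
  the false-fissure phenomenon that motivates the improved extraction pass.
  The drop of `D` one voxel off the ridge, in units of the local one-voxel
  increment `h / F`, separates head-on collisions (≈ 0.5 on the phantom) from
  these glancing shocks (≤ 0.2); the default threshold is 0.25.
* **Thinning.** Candidates are reduced by recursive geodesic erosion — simple
  points removed in increasing-`D` order under a local-thickness guard (only
  voxels with ≥ 9 foreground 26-neighbours are eligible, so an open one-voxel
  sheet is never peeled from its free edges) — and isolated specks below 6
  voxels, which topology-preserving erosion cannot remove, are dropped.

Resistant layers (near-zero speed barriers between anatomically distinct but
touching lobules, e.g. vermis lobules 1 and 10) block the front; their voxels
are excluded from the ridge domain and never carry fissure.

The **improved pass** replaces intensities at the initial Purkinje mask with
a multi-level (default 10) masked Gaussian average of surrounding cortex and
re-runs speed, distance, and ridge detection, so the second extraction relies
on the fissure's own contrast rather than the lamina's.

### Laplace and equivolume laminar model

On the cortical domain (GM minus fissure/resistant voxels) the Laplace
equation is solved by Jacobi iteration with Dirichlet conditions `psi = 1` at
WM and `psi = 0` at the pial boundary (mask boundary united with extracted
fissures). Boundary conditions are taken to hold on the voxel *face* between
a domain voxel and a boundary voxel (a Shortley–Weller half-spacing stencil):
with conditions at boundary-voxel centres the discrete shell solution
corresponds to radii shifted by half a voxel, an error of ~0.1 in `psi` near
the boundaries at 0.04 mm spacing — far outside the 0.02 accuracy the
validation targets. In-cortex sheets (extracted fissures, the Purkinje
lamina) are the exception: they are one-voxel structures whose surface *is*
the voxel centre, so their distance factor is 1.0.

The unit field `F = grad psi / |grad psi|` points WM-ward. From each cortical
voxel a streamline is traced both ways (fixed step `dl`, default a quarter
voxel; trilinear interpolation; the terminal segment is clipped at the
boundary by bisection), evolving a unit surface element multiplicatively,
`ds[n+1] = ds[n] (1 + dl div F)` — the update accumulates the relative
surface-area change along the tube of streamlines. The equivolume depth is
`R_vol = V_pial / (V_pial + V_WM)` with `V = sum(ds dl)` accumulated toward
each boundary: 0 at the pia, 1 at WM, and equal to the *volumetric* depth
fraction, which places iso-depth surfaces toward the lower-curvature side of
a fold exactly as the histology-motivated equivolume principle requires. On
a spherical shell the `R_vol = 0.5` surface sits at
`r*^3 = (r_in^3 + r_out^3) / 2`; the solver reproduces it to < 0.1 voxel.

### Purkinje extrapolation and layer segmentation

The equivolume depth observed at the initially detected Purkinje voxels is
propagated over the cortex by multi-level masked Gaussian smoothing (10
levels of sigma = 1 voxel; observed values stay fixed), giving the
extrapolated Purkinje depth surface `R_P^S`. The mismatch
`lambda = |R_vol - R_P^S|` vanishes where a voxel sits at the extrapolated
Purkinje depth; directional local minima of `lambda` along the streamline
direction with `lambda` below a closeness tolerance (default 0.05 ratio
units) are added to the mask. The marked set is thinned by the same
geodesic-erosion operator (ordered by decreasing mismatch) because the
±1-voxel trilinear comparison admits straddling duplicates; thinning removes
them without eroding the sheet.

Granular and molecular layers are the two sides of the remaining cortex
relative to the final Purkinje sheet: connected components of `GM \ M_PF`
are assigned to the boundary (WM or pial) they touch. Components reachable
from both are leaks — holes in the sheet — and are split by unit-speed
geodesic distance to the two boundaries and reported voxel-by-voxel rather
than failing. The three masks partition the cortical domain exactly.

### Thickness

Thickness is the arclength of the field streamlines between boundaries,
computed by the Eulerian PDE method: upwind Gauss–Seidel iteration of
`grad L0 . F = 1` (zero on the inner boundary) and the pial-ward analogue,
`T = L0 + L1` in mm, without explicit tracing. The full-cortex `T_GM` keeps
the lamina inside the domain (its arclength counts); the layer thicknesses
`T_Gran` (WM to lamina) and `T_Mol` (lamina to pia) exclude it, so
`T_Gran + T_Mol` falls short of `T_GM` by about one voxel — the phantom
reproduces that decomposition. All three are sampled at each Purkinje voxel
("vertex") by trilinear interpolation, falling back to the mean of valid
26-neighbours against the sheet.

### Morphometry and statistics

Per (structure, layer): volume is voxel count times voxel volume; thickness
is the mean per-vertex value over the structure's Purkinje vertices (a vertex
belongs to the structure labelled at its voxel); surface area is
volume / thickness; and TSR is thickness / sqrt(area), a dimensionless shape
descriptor computed from raw (non-normalized) measurements. The default
16-structure lobule codebook is reduced to 14 analyzed ROIs by merging
lobules 1 and 2 and excluding Cop (it sits against artificial processing
boundaries).

Head size is regressed out by W-scores: per cell, ordinary least squares of
the metric on TIV over *controls only*; every subject's residual is
standardized by the control residual mean and sd. Control W-scores have mean
0 and sd 1 exactly by construction. Structure-level group differences use
two-sided pooled-variance t-tests on W with Benjamini–Hochberg FDR control at
q = 0.1 within each (layer × metric) family, mirroring per-panel reporting.
Vertex-wise comparisons use per-vertex t-tests with family-wise max-T
permutation correction (seeded label permutations; exhaustive enumeration
when fewer distinct reassignments exist than requested). Permutation replaces
random-field-theory cluster correction deliberately: RFT needs smoothness
estimation and a cluster-forming threshold that are unspecified for this
voxel-sheet setting, whereas permutation is exact under exchangeability.

## The phantoms: what they emulate, and what they do not

* `make_shell()` — a WM ball in a cortical shell (defaults r_in = 0.4 mm,
  r_out = 0.64 mm at 0.04 mm isotropic spacing, matching the emulated
  acquisition grid) with a one-voxel bright lamina at the equivolume locus.
  Closed forms exist for the potential, the equivolume radius, layer volumes
  and thicknesses.
* `make_folded_slab()` — a constant-thickness cortical band over a sinusoidal
  WM surface. With the default amplitude (0.7 mm at 0.8 mm wavelength,
  0.2 mm cortex) the valley walls touch and the analytic contact mid-surface
  is the true fissure; a gentle geometry keeps the gap open and the true
  fissure set empty. An optional resistant mask bars one valley.
* `simulate_cohort()` — a two-group morphometry cohort (defaults 14 + 14
  subjects, the emulated study size) with TIV-correlated metrics
  (slope 1 control-SD per control-SD of TIV), a +30 mm³ case TIV shift,
  −1.5 control-SD granular thickness and −1.5 control-SD molecular surface
  area in cases, residual CV 5%, and deterministic per-structure baselines
  (granular thickness ~0.12–0.24 mm). Volume is thickness × area by
  construction.

Noise is additive Gaussian on intensity. The phantoms do **not** simulate MR
physics: no bias fields, no Rician floor, no T2*/Gd uptake variation, no
partial-volume anti-aliasing (phantom edges are hard), and no registration
error — lobule labels and masks are inputs throughout, as atlas propagation
is out of scope. Passing phantom validations therefore establishes the
*numerical correctness* of each operator against its governing model, not
robustness to acquisition artefacts; the hard-edged lamina in particular
means the planeness filter's fringe behaviour (about 2% of lamina-mask
voxels at the voxelized ribbon edge flip the sign of the tangential second
derivative and score zero) is assessed with a one-voxel sheet-coverage
criterion.

## Numerical choices

* Jacobi tolerance 1e-6 (max update), cap 20 000 iterations; domain voxels
  not 26-connected to both boundaries are excluded and reported.
* Fast marching is first-order upwind with a binary heap; unreached voxels
  keep the `Inf` sentinel.
* Eulerian thickness: alternating-order upwind sweeps, tolerance 1e-4 mm.
* Streamline step `dl = 0.25 ×` spacing, cap 10× domain diagonal / `dl`;
  capped traces are flagged and imputed from valid neighbours.
* Otsu's threshold on positive within-GM responses is the deterministic
  default for the initial Purkinje mask.
* EM: relative log-likelihood tolerance 1e-6, 500 iterations, quantile-based
  initialization, up to 5 seeded restarts on collapse.
* Component connectivity is 26 for tissue objects; 6 for the complement
  argument in layer separation (the standard foreground/background duality
  for one-voxel separating sheets). Equal-size component ties break to the
  lexicographically first seed voxel, with a message.
* Degenerate inputs: empty layers yield zero thickness with a message; zero
  TIV variance falls back to an intercept-only W-score model with a warning;
  empty fissure sets are valid outputs.

## Validation problem sizes

The shipped validation suite runs shells of ~41³ voxels (≈13 000 cortical
voxels), folded slabs of 40×12×31, a 20³ random-speed Eikonal oracle grid,
1000-replicate null calibrations at 50 subjects per group, and effect
recovery at 200 per group — sizes at which every closed-form comparison in
the acceptance suite resolves well inside its tolerance while the whole
suite stays interactive.

## Known limitations

* W-scores standardized by a control fit are mildly anti-conservative for
  very small control groups: at 14 controls the measured null per-family
  any-rejection rate is ≈ 0.128 at q = 0.1 (the control residuals are shrunk
  by the fit, cases are not). The calibration check therefore runs at 50 per
  group, where the effect is negligible; at real-study sizes the practitioner
  should treat borderline q ≈ 0.1 flags with this in mind.
* The spec-level contract "R_vol < 0.1 adjacent to the pial boundary" is not
  attainable at 0.04 mm spacing for the 0.4/0.64 mm shell — the closed form
  itself averages ≈ 0.11 at the centres of boundary-adjacent voxels; the
  validation compares against the closed form instead.
* Ridge prominence (0.25) cleanly separates contact creases from lamina
  shocks on the phantoms; on real data with weaker fissure contrast the
  threshold is exposed (`min_prominence`) and may need lowering together
  with a review of the resistant-layer placement.
* The per-vertex correspondence for vertex-wise statistics is identity
  (phantoms share geometry). Real cohorts need the upstream registration
  that is explicitly out of scope here.
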