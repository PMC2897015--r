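---
title: "Methods: DVH computation, plan indices and outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DVH computation, plan indices and outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planDVH)
```

## The problem

A radiotherapy treatment plan assigns absorbed dose (cGy) on a regular 3D
voxel lattice, while the anatomy — planning target volumes (PTVs) and organs
at risk (OARs) — is delineated as closed planar contours on CT slices. Almost
every quantitative statement about plan quality reduces the 3D dose
distribution over a structure to its dose–volume histogram (DVH): the
differential DVH (dDVH) bins structure volume by dose, and the cumulative DVH
(cDVH) gives the volume receiving at least each dose level. This package
computes these histograms from first principles (contours + dose grid),
extracts arbitrary statistics from them, and layers three evaluation tools on
top: spatial DVH derivatives (per-slice zDVH, dose-surface histogram DSH), a
ten-index conformity/homogeneity score set with an overall quality factor,
and Poisson/Lyman outcome models (TCP, NTCP).

## Rasterization

Contours are converted to voxel membership with an even-odd (ray-crossing
parity) point-in-polygon test applied to voxel *centers*; points exactly on a
contour edge count as inside. The even-odd rule means nested rings carve
holes, which is how annular cross-sections (spherical-shell organs) are
encoded without any special casing. The coordinate convention is patient
millimeters with the grid origin at the center of voxel (0,0,0), so a sample
point is always the unambiguous center of the region it represents.

With `supersample = k` (k in 1..4), each voxel is probed at a stratified
k×k in-plane sub-grid and its membership weight is the fraction of sub-points
inside — a partial-volume treatment whose fractional weights propagate into
every histogram downstream. `supersample = 1` reproduces pure voxel counting.
Because contours are planar and coincide with grid slices, sub-sampling along
z would test the same polygon and is therefore not performed.

## DVH construction

The dDVH uses uniform half-open bins [lo, hi); the default bin width is
(max grid dose)/500, which yields cumulative curves sampled at 501 dose
points — the resolution used throughout. Two exact quantities are carried
alongside the binned volumes:

* the per-bin first dose moment (sum of dose × volume), so the mean dose is
  exact regardless of bin width, and
* the observed min/max voxel dose.

The cumulative curve treats each bin's volume as uniformly spread across the
bin: it is exact at every bin edge and linear inside a bin. This makes
V(D) at a threshold equal to the max dose behave correctly (a structure
uniformly at dose D has V(D) equal to its full volume), at the cost of
smearing at most one bin width of dose. One consequence is documented and
handled explicitly: inverse lookups (median, Dx) carry half-a-bin resolution
and could nominally exceed the exact maximum dose on a degenerate
single-dose structure, so all Dx-type results are clamped to the observed
[min, max] dose range.

## Smoothing and statistics extraction

Statistics that invert the curve (Dx, median = D50) use a continuous model
of the cDVH. Between each pair of adjacent samples a transition point is
synthesized by cosine interpolation with weight factor 0.5 — the cosine
blend g(t) = (1 − cos πt)/2 evaluated at the midpoint t = 0.5, i.e. the
equal-weight blend of the two neighbors. A least-squares polynomial is then
fit over that midpoint plus the six nearest samples. The polynomial degree
is not fixed a priori: each window picks its degree from {2, 3, 4, 5} by
minimal leave-one-out RMSE (computed via the hat-matrix identity), with ties
broken toward the lowest degree — a reproducible reading of "optimal
polynomial" fitting.

A least-squares fit does not interpolate its data, but evaluation at an
original sample dose must reproduce that sample. Both requirements are met
by clipping each window's fitted values to its bracketing samples and
passing a dense per-window evaluation table through a running minimum: the
curve is monotone non-increasing *by construction*, pinned to the data at
every sample, and still polynomial-smooth between samples. Inverse lookups
linearly invert this monotone table.

Queries outside the modeled dose range are clamped to the curve endpoints
and flagged (`clamped`), never extrapolated.

## Curve comparison metrics

Two curves are compared on the fraction-of-own-total scale (published NRMSD
conventions differ, so the normalization is stated prominently: by total
structure volume). NRMSD is 100 × the RMS pointwise difference at the probe
doses; DTA is 100 × |D_a(V) − D_b(V)| / PD at a volume level V, by default
50% of the structure volume. Both accept computed curves, smoothed models,
or closed-form functions interchangeably.

## Plan indices and quality factor

The ten scored indices are TCI, COSI, RCI, PITV, HI, MHI, CN, TVR, DGI and
NCI, with CI and TR kept as auxiliaries rather than scored members (the
scored set has exactly ten names; CN and CI are linked by CN = TCI·CI and
CI = 1/TR, identities the tests enforce). COSI is evaluated as
1 − [Σ wᵢ·V(OARᵢ ≥ TOLᵢ)]/TCI with default weights wᵢ = 1/N — the grouping
chosen where the typeset formula is ambiguous, consistent with the stated
per-organ weight of 1/N. The prescription isodose volume (PIV) is measured
over the *whole dose grid*, not the target, which is what distinguishes PITV
from coverage ratios. No clinical tolerance-dose table is bundled: TOLᵢ is
always user-supplied. Vanishing denominators yield `NA` plus a reason, never
±Inf.

The quality factor is QF = 2.718·exp(−Σ Wᵢ Xᵢ). The printed constant 2.718
is kept literally rather than replaced by e, so the ideal plan (all Xᵢ = 1,
Wᵢ = 0.1) scores 2.718/e ≈ 0.99990; tests use a 10⁻³ tolerance on that
anchor.

## Outcome models

The Poisson TCP model is
TCP = (1/2)^(Σ vᵢ exp[2 γ₅₀ (1 − Dᵢ/TCD₅₀) ln 2]) on a fractional DVH
(Σ vᵢ = 1, enforced to 10⁻⁹). A uniform dose at TCD₅₀ gives exactly 50%
control. Zero-dose bins are *not* dropped: Dᵢ = 0 contributes
exp(2 γ₅₀ ln 2) to the exponent, and 0 to the generalized mean dose.

NTCP uses the sigmoidal (probit) dose response
NTCP = Φ[(EUD − TD₅₀)/(m·TD₅₀)], where Φ is the standard normal CDF —
implemented with R's `pnorm`, equivalently Φ(x) = ½·erfc(−x/√2) — and
EUD is the generalized mean dose GMD = (Σ vᵢ Dᵢ^{1/n})^n. The GMD is
computed on the scale of the maximum dose, GMD = Dmax·(Σ vᵢ (Dᵢ/Dmax)^{1/n})^n,
so exponents 1/n up to 1000 cannot overflow. When converting a binned dDVH
to fractional form, Dᵢ is the bin midpoint dose.

Example parameters shipped with the package (prostate target, rectum):
TCD₅₀ = 4180 cGy, γ₅₀ = 0.6; TD₅₀ = 8190 cGy, m = 0.19, n = 0.23 — worked
example values, not clinical recommendations.

## Spatial derivatives

The zDVH is one dDVH per axial slice on shared bin edges; summing the slice
histograms bin-by-bin reproduces the whole-structure dDVH exactly (a
conservation identity tested to machine precision). The DSH restricts the
dDVH to boundary voxels, defined by 6-connectivity: a member voxel with at
least one face neighbor outside the mask or outside the grid. "Surface" has
no unique voxel-level definition; one-voxel 6-connectivity erosion is the
simplest reproducible choice, and a contour-distance surface is a documented
alternative left unimplemented. Hot/cold slice flags (max > 1.05 PD,
min < 0.95 PD) are a reporting convenience with explicitly chosen
thresholds.

## The synthetic phantom generator

The generator is the package's fixture factory and oracle source: geometric
targets (sphere, box) and shell/offset-sphere OARs, with three analytic dose
models — uniform plateau, linear radial falloff
D(r) = D₀·max(0, 1 − (r − R)/L), and two-level — plus optional seeded
additive Gaussian noise clipped at 0 cGy. Circular cross-sections are
contoured as inscribed 64-gons, and the closed-form curves idealize true
spheres, so a ~0.2% polygonization deficit is part of the comparison budget.
The reference phantom is a 20 mm radius spherical target with a 10 mm linear
falloff and a 20–30 mm shell OAR on a 66³ grid at 1 mm isotropic spacing,
D₀ = PD = 6000 cGy, which keeps every test under a minute on one CPU; unit
tests use 2 mm variants of the same geometry for speed, at proportionally
relaxed lattice-accuracy thresholds.

What the phantoms deliberately do not emulate: realistic beam models, tissue
heterogeneity, CT artifacts, inter-observer contouring variability, or the
irregular structure shapes of clinical anatomy. Passing the analytic-oracle
envelope (NRMSD < 1% of total volume, DTA at 50% volume < 0.5% of PD at
1 mm / 501 bins) demonstrates the correctness and convergence of the
histogram machinery, not clinical equivalence to any treatment planning
system.

## Exchange format and reports

The plan-bundle dialect is a deliberately simple plain-text stand-in for
planning-system exports (one header file, one ASCII dose file per plan, one
contour file per structure), carrying the same information content; a
genuine RTOG/DICOM-RT adapter is a seam left for the future. Floats are
written with 17 significant digits so write–read round trips are exact.
Reports are CSV (diffable, byte-deterministic) in four sections — target
summary with PD-fraction coverage, normalized and absolute coverage of
normal structures, and Vx/min/max/mean/median statistics — with percent
cells rounded half-up to whole percents.

## Known limitations

* Dose is sampled voxel-wise; no dose-grid interpolation beyond sub-voxel
  membership sampling, so accuracy is lattice-limited (the tests quantify
  this against closed forms).
* Contour slices are matched to the nearest grid slice within half a slice
  spacing; out-of-plane (oblique) contours are unsupported.
* The DSH surface is voxelized, not the true contour surface.
* Composite-plan handling assumes component dose grids share one lattice.
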