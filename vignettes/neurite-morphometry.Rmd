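---
title: "Neurite morphometry from tubular volumes: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurite morphometry from tubular volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogeom)
library(tibble)
library(dplyr)
```

## The problem

Golgi-stained brain tissue imaged by synchrotron X-ray nanotomography shows
neuronal processes as bright tubes (radius roughly 0.2–2 µm) on a dark
background, at voxel sizes near 100 nm. Comparative morphometry of such
volumes asks: do the shapes of neurites — their curvature, torsion,
thickness, and the lengths and radii of their dendritic spines — differ
between brain areas, between individuals, and between patient and control
groups?

`neurogeom` implements that workflow end to end: synthetic phantoms with
closed-form ground truth, volume I/O, centerline tracing, a plain-text
structural-model format, discrete differential geometry, and the group-level
statistical battery. Because raw nanotomography volumes of this kind are not
generally available, every quantitative claim in the package is validated on
phantoms whose geometry is known exactly.

## Geometry estimators

A traced constituent is an ordered node chain $p_1,\dots,p_n$ with thickness
radii $r_i$ (all in µm). The estimators are deliberately parameter-free:

* **Curvature** at interior node $i$ is Menger curvature, the reciprocal
  circumradius of the triangle $(p_{i-1}, p_i, p_{i+1})$:
  $\kappa_i = 4A_i / (|p_i-p_{i-1}|\,|p_{i+1}-p_i|\,|p_{i+1}-p_{i-1}|)$.
  It is exact on circles and zero on collinear triples. A fitted-spline
  estimator was considered and rejected: it would introduce a smoothing
  bandwidth whose choice the data cannot justify.
* **Torsion** on edge $i$ is the angle between consecutive discrete
  binormals $b_i = (e_{i-1}\times e_i)/|e_{i-1}\times e_i|$ divided by the
  edge length, signed by $(b_i \times b_{i+1})\cdot\hat e_i$; a right-handed
  helix is positive. Because the discrete binormal is a *line*, not a
  vector, it flips sign at in-plane inflections; the implementation
  re-orients each consecutive pair so planar zig-zags read exactly zero. A
  chain that is exactly straight has no binormal at all; its torsion is
  reported as 0 (a straight line is planar).
* **Averages** are arc-length weighted (interior-node weights are the mean
  of the two adjacent edge lengths), which makes them robust to the uneven
  node spacing a tracer produces; `weighting = "node"` switches to the plain
  mean for sensitivity checks. For an $n$-node chain there are $n-2$
  curvatures, $n-3$ torsions, and $n-1$ edges. Nodes closer than $10^{-6}$
  µm are merged before any cross products are formed.
* **Spine length** is the path length plus the segment from the parent
  attachment node to the spine's first node, so it measures from the parent
  centerline. Whether that attachment segment belongs to the spine is a
  convention; including it matches the tracer, whose spine traces begin one
  mask-standoff away from the parent axis.

On analytic curves these converge with order at least one in the sampling
step; the test suite pins the helix $(a, b) = (1, 0.5)$ µm at
$\kappa = a/(a^2+b^2) = 0.8$ and $\tau = b/(a^2+b^2) = 0.4$ µm$^{-1}$ to 1%
at 600–800 samples.

## The tracer

The published description of tracers for this kind of data names two
ingredients — a 3D Sobel gradient and gradient vector flow (GVF) — with the
remaining policies applied by hand-editing. `neurogeom` instead fixes every
policy explicitly so runs are reproducible:

1. **Gradients.** Separable Sobel ([−1,0,1] derivative, [1,2,1] transverse
   smoothing, mirror boundaries, scaled 1/32 to intensity-per-voxel).
2. **GVF.** $v \leftarrow v + \mathrm{d}t\,[\mu\nabla^2 v - |g|^2(v-g)]$
   from $v_0 = g$ with $\mathrm{d}t = 1/(6\mu + \max|g|^2)$. That step size
   is below the descent-stability bound for the energy
   $E = \sum \mu|\nabla v|^2 + |g|^2|v-g|^2$, so $E$ is monotonically
   non-increasing — asserted per iteration in the tests. Defaults
   $\mu = 0.2$, 80 iterations: enough diffusion to fill tubes up to ~8
   voxel radius.
3. **Seeds.** Voxels above `background + 3σ` (σ of the raw voxel-value
   distribution — the same unit used to contour such tomograms at 3.0 σ)
   that locally maximize $-\nabla\cdot\hat v$, the convergence of the
   normalized GVF field. Seeds are processed thickest-first (a quick
   ray-cast radius at each seed), so trunks are traced before the lateral
   processes that branch off them; otherwise a spine traced first would
   claim the junction and fragment its parent.
4. **Marching.** Bidirectional from the seed; the tangent is the
   least-variance eigenvector of the local gradient covariance (a 5³ window
   that grows up to 25³ inside thick tubes, where the interior is
   gradient-free); each step advances 1.5 voxels, re-centers along the GVF
   component orthogonal to the tangent, then refines the point by ray
   symmetry — opposite boundary-crossing pairs vote on the centre. The
   march stops below `background + 1.5σ`, at the volume margin, at
   `max_nodes`, or on entering the visited mask (dilated by each node's
   radius plus one voxel).
5. **Smoothing.** The finished chain is moving-averaged over a 5-node
   window (`smooth_window`, 1 disables). This is a tracer policy, not a
   geometry option: sub-voxel re-centering jitter of amplitude $\epsilon$
   inflates Menger curvature by roughly $2\epsilon/h^2$ at step $h$, which
   at $h = 0.15$ µm would dominate real curvatures of order 0.5 µm$^{-1}$.
   With ray re-centering plus the window, a noise-free helix of true
   curvature 0.4 µm$^{-1}$ traces to 0.385–0.39.
6. **Radius.** Median of `ray_count = 12` boundary crossings at the
   half-maximum of (centre − background), located to sub-voxel precision by
   linear interpolation along each ray. Accuracy on noise-free tubes of
   radius 2–8 voxels is 1–5%.
7. **Classification.** After all traces finish, chains longer than
   `spine_cutoff_um = 3` µm are neurites (typical spines are at most a few
   µm); shorter chains whose end lies within parent radius +
   (2 + step) voxels of a neurite node become spines attached at the
   nearest node, and the rest stay neurites. The allowance includes one
   march step because a spine's first traced node sits just outside the
   parent's visited mask. True bifurcations are not resolved: each trace is
   unbranched, and a branch appears as a separate constituent.

## Phantoms and what they do (and do not) show

`render_volume()` draws each curve as a soft tube: the indicator falls
linearly from 1 to 0 over one voxel centred at the local radius, emulating
partial-volume blur and giving the tracer the same sub-voxel edge
information a real tomogram carries; additive Gaussian noise (seeded) and a
[0, 1] detector range complete the model. Ground-truth models are the same
curves resampled at 2-voxel node spacing — comparable to the node spacing of
hand-built models on a ~100 nm grid.

The phantoms deliberately do *not* simulate X-ray physics, reconstruction
artefacts, stain granularity, crossing or touching neurites, somata, or
vasculature. Passing the recovery tests therefore shows that the tracer and
estimators are correct on clean tubular geometry at realistic contrast and
noise; it does not certify performance on dense real tissue, where manual
editing was part of the original workflow.

## The synthetic cohort

`generate_geometry_cohort()` emulates the *statistical* structure of a
two-area, eight-case study directly at the geometry-table level: four cases
per group, two areas, `datasets_per_case_area = 2` image datasets per cell,
and hundreds of constituents per dataset. Per-constituent mean curvature is
lognormal; its location is `log(base + group offset + area offset)` plus a
per-case effect `N(0, case_sd)`. Defaults — base 0.5 µm$^{-1}$, patient
offset +0.1, `case_sd = 0.25`, `sdlog = 0.45` — put case means in the
0.3–1.1 µm$^{-1}$ range that brackets the published per-case means
(0.35–1.08), with the patient group modestly higher. `case_sd` is this
package's addition: without a per-case dispersion there is no "stepwise
case-to-case variation" to emulate; setting it (and the offsets) to zero
yields the exchangeable null used for calibration.

With `coupling = TRUE`, radii satisfy $r = c/\kappa$ exactly per
constituent. Because the lognormal spread is constant across cells, cell
means obey $\log \bar r = \log c + \sigma^2 - \log\bar\kappa$ exactly in
expectation, so the log–log regression of $\bar\kappa$ on $\bar r$ has slope
exactly −1 before sampling noise. The Monte-Carlo standard error of the
fitted exponent is approximately
$\sqrt{2}\,\mathrm{cv}(\kappa) / (\sqrt{n_\text{cell}}\,\sqrt{14}\,\mathrm{sd}(\log \bar r))$;
the recovery runs use 10 000 constituents per cell and `case_sd = 0.4` so
that error (~0.006) sits well inside the asserted ±0.02 band.

## Statistics

The battery wraps base R behind a stable surface: Welch's ANOVA
(`oneway.test`), balanced two-way fixed-effects ANOVA on case-area means
(`lm`/`anova`; with interaction, error df $= n-4$, i.e. 12 for 8 cases × 2
areas; `interaction = FALSE` gives 13 — both are offered because a printed
F value alone cannot disambiguate them), Bartlett's variance check, two-sided
two-sample Kolmogorov–Smirnov per case across areas with Holm–Bonferroni
step-down correction (exact p when $nm \le 10^4$, asymptotic otherwise —
per-case samples of hundreds to thousands are in the asymptotic regime),
type-7 quantiles, and the two structure fits (OLS spine-on-neurite radius;
log–log curvature–radius power law). Every test is cross-checked in the
suite against an independently hand-coded oracle (Welch $F^*$, balanced
sums of squares, Bartlett $\chi^2$, the KS series, the Holm recursion) to
$10^{-8}$.

The unit of analysis for Welch's ANOVA is the dataset mean grouped by case,
not pooled per-neurite values: the distribution panels of such studies plot
dataset means with error bars, and an F near 90 on 8 cases is consistent
with ~34 dataset-level observations, not thousands of neurites.

Calibration, verified by simulation in the tests and recomputed by the
acceptance script: Welch's type-I error at the 8-case design is 0.05 ± 0.02
with ~10 values per case (the Welch–Satterthwaite approximation is known to
inflate a further 1–3 points when groups shrink to 4–6, which the suite
avoids asserting as if it were an implementation defect); the Holm KS family
(7 simultaneous tests) keeps FWER ≤ 0.05; and the null cohort generator
yields uniform two-way group-effect p values. A power note: with one mean
per case and area (8 cells per group), the exact power of the (1, 12)-df
F test at a 1-between-cell-sd group offset is only ~0.46, so "detects the
designed effect" is asserted at 2 sd (theoretical power ~0.9), and the
cohort default offset (+0.1 µm$^{-1}$ with `case_sd = 0`) is comfortably
detectable.

## Formats

Models travel in a fixed-column PDB dialect, self-described in `REMARK 300`
headers: one ATOM per node, resName encodes the constituent type
(NEU/APD/SPI/SOM/VES), chainID cycles A–Z then 0–9 with resSeq
disambiguating past 36 chains, coordinates are micrometres (not Å) in the
8.3 fields — tissue blocks are µm-scale, and the field then spans ±999.999
comfortably — and the thickness radius rides in tempFactor (the only spare
numeric field), to 2 decimals. CONECT joins consecutive nodes and each
spine's first node to its parent node; write→read→write is byte-identical.
This dialect is an explicit stand-in — the field mapping of the original
model-building software is not published — and says so in its headers. SWC
export (soma 1, neurite 2, apical dendrite 4, spine 5, vessel 7) is offered
because SWC is the community standard for neuron morphology.

Volumes are multipage float TIFF (or directories of slices) with voxel size
and origin in a JSON sidecar, since the TIFF writer available here exposes
no resolution tags. Axis order is fixed `(z, y, x)`; physical µm =
(index − 1) × voxel/1000 + origin. Anisotropic voxels are out of scope.

## Pipeline

`run_pipeline()` chains normalize → trace → write model → geometry table →
statistics, with per-dataset blinding: models are built and written under
seeded opaque codes (`assign_blind_codes()`), and case labels are joined
only afterwards, mirroring the blinded model-building of the original
workflow. A coverage check flags cases whose aggregated neurite count is
strictly below 500 (configurable). One config seed fans out to per-stage
seeds through a multiplicative-congruential derivation (`derive_seeds()`),
and a rerun with the same config is byte-identical in every CSV, JSON, and
model output. Timings live only in the log file so they cannot break
determinism.

## Problem sizes used in the checks

Phantom recovery runs use 128³ voxels at 100 nm (the tube, noise, and helix
cases) and 72³ for the spiny neurite; calibration uses 500–600 simulation
replicates; cohort recoveries use 16 case-area cells with up to 10 000
constituents each; the demo pipeline runs eight 48³ volumes twice to assert
byte-level determinism. These sizes make every assertion tight while a full
`devtools::test()` stays in the minutes range on one CPU.

## Known limitations

* Unbranched traces only; bifurcations yield separate constituents and are
  flagged by proximity, not resolved.
* The tracer assumes bright-on-dark tubular contrast; it has no model of
  touching structures, hollow stains, or reconstruction streaks.
* Radius estimates degrade below ~1.5 voxel radius (the soft edge then
  spans most of the tube).
* Welch's ANOVA calibration degrades at very small per-case counts; that is
  a property of the method, not of this implementation.
* The PDB dialect caps coordinates at ±999.999/9999.999 µm per the fixed
  field width and warns when chain IDs recycle.
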