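# neurogeom

Geometric analysis of neuronal processes in 3D grayscale volumes.

Golgi-stained brain tissue imaged by X-ray nanotomography (voxels ≈ 100 nm)
shows neurites and dendritic spines as bright tubes on a dark background.
`neurogeom` turns such volumes into quantitative morphometry and runs the
group-level comparisons used to ask whether neuron shape differs between
brain areas, between individuals, and between patient and control groups:

* **Phantoms** — parametric space curves (line, circle, helix, smooth
  random) rendered as noisy tubular volumes with closed-form ground truth,
  plus a cohort-level generator with designed group/area effects and an
  exact `κ = c / r` curvature–radius coupling.
* **Volume I/O** — multipage / slice-directory TIFF with voxel-size
  metadata, `[0, 1]` normalization reporting the raw mean and σ so
  thresholds can be stated in σ units.
* **Tracing** — centerline extraction from 3D Sobel gradients and gradient
  vector flow (GVF): seed detection by GVF convergence, bidirectional
  marching with GVF + ray-symmetry re-centering, median-of-rays radius
  estimation, and automatic neurite/spine classification with attachments.
* **Models** — node-chain structural models in a fixed-column, self-describing
  PDB dialect (µm coordinates, radius in tempFactor, CONECT connectivity;
  byte-exact round trips), with SWC export.
* **Geometry** — per-constituent Menger curvature, signed binormal torsion
  (right-handed positive), arc-length-weighted means, lengths, radii.
* **Statistics** — Welch's ANOVA across cases, balanced two-way
  group × area ANOVA, Bartlett, per-case two-sample Kolmogorov–Smirnov with
  Holm–Bonferroni correction and the `****`/`***`/`**`/`*` star scheme,
  quartiles, and the structure fits (spine-vs-neurite radius OLS, log–log
  curvature–radius power law).
* **Pipeline** — `run_pipeline()` chains everything with blinded dataset
  codes, a <500-neurite coverage check, CSV/JSON outputs, and bytewise
  deterministic reruns under one seed.

The core estimators in the field's notation: Menger curvature at node
$p_i$,

$$\kappa_i = \frac{4A_i}{|p_i-p_{i-1}|\;|p_{i+1}-p_i|\;|p_{i+1}-p_{i-1}|},$$

and discrete torsion from consecutive unit binormals
$b_i = (e_{i-1}\times e_i)/|e_{i-1}\times e_i|$,
$\tau_i = \theta(b_i, b_{i+1})/|e_i|$ signed by
$(b_i\times b_{i+1})\cdot\hat e_i$. A helix with radius $a$ and pitch
parameter $b$ has $\kappa = a/(a^2+b^2)$, $\tau = \pm b/(a^2+b^2)$ — the
package's primary ground truth.

## Worked example

Trace a noisy helical phantom and recover its differential geometry:

```r
library(neurogeom)
library(dplyr)

helix <- make_parametric_curve("helix", list(a = 2, b = 1, turns = 1.5,
                                             center = c(3.55, 3.55, 0.8),
                                             radius = 0.4), 200)
spec  <- phantom_spec(shape = c(128, 72, 72), voxel_size_nm = 100,
                      curves = list(list(polyline = helix)),
                      noise_sd = 0.035, seed = 7)
ph    <- render_volume(spec)
model <- trace_model(normalize_volume(ph$volume)$volume)
geometry_table(model) |>
  select(constituent_id, type, n_nodes, length_um,
         mean_curvature, mean_torsion, mean_radius)
#> # A tibble: 1 × 7
#>   constituent_id type  n_nodes length_um mean_curvature mean_torsion mean_radius
#>   <chr>          <chr>   <int>     <dbl>          <dbl>        <dbl>       <dbl>
#> 1 N001           neur…     146      21.8          0.394        0.129       0.398
```

The true values for this helix are curvature
$2/(2^2+1^2) = 0.4$ µm⁻¹ and thickness radius 0.4 µm: the trace recovers
both within a few percent from a volume with 5%-of-contrast noise (torsion,
a third difference of noisy positions, is recovered more loosely).

Cohort-level statistics run on tables, not volumes:

```r
ch  <- generate_geometry_cohort(cohort_spec(seed = 1))
cam <- case_area_means(ch$geometry, parameter = mean_curvature,
                       types = "neurite")
tidy(two_way_anova(cam))
#> # A tibble: 3 × 6
#>   term          df     sumsq statistic p.value stars
#>   <chr>      <int>     <dbl>     <dbl>   <dbl> <chr>
#> 1 group          1 0.0426      2.00      0.183 ns
#> 2 area           1 0.000144    0.00677   0.936 ns
#> 3 group:area     1 0.0000363   0.00170   0.968 ns
```

Under the default generator the designed +0.1 µm⁻¹ patient-group offset
competes with realistic case-to-case heterogeneity (`case_sd = 0.25`), so a
single 8-case cohort is — as in real studies of this size — not guaranteed
to reach significance; set `case_sd = 0` to see the offset detected at
p ≪ 0.001. `ks_holm()`, `welch_anova()`, `dataset_summary()`,
`radius_correlation()` and `curvature_radius_fit()` follow the same
data-frame-in, tibble-out pattern, and `autoplot()` /
`plot_distribution_by_dataset()` give the standard figures.

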