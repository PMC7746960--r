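# foveamosaic

Analysis of foveal cone photoreceptor mosaics from adaptive optics scanning
light ophthalmoscopy (AOSLO), for imaging groups that study photoreceptor
topography and for trialists who want to use the fellow eye as a
within-subject control. The package starts where cone detection ends: its
input is a list of cone-centre coordinates over a ~300 x 300 um foveal
crop, plus a um/pixel scale (or the axial length to derive it).

From that point pattern it computes:

* **Image scale** — `SR(x)' = (T / (T_s f_l)) (180/pi) RMF (l_A / l_A0)`,
  the Ronchi-ruling-calibrated magnification model with RMF = 291 um/degree
  at the 24.0-mm reference axial length.
* **Sum-maps** of bound-cell density (cones/mm^2), inter-cell distance
  (ICD, um) and Voronoi cell area regularity (VCAR = mean / SD of bound
  cell areas). A square window centred on each cone grows until it holds
  100 *bound* Voronoi cells (finite polygons fully inside the window); each
  map pixel averages all windows covering it. Peak cone density and its
  location are extracted from the density map, with spacing and VCAR read
  off at that location.
* **Isodensity contours** at 70/75/80/85/90% of peak density, each scored
  by the roundness (`Minor/Major` of the moment-equivalent ellipse) and
  enclosed area; plus the VCAR comparison inside vs outside the 80%
  contour.
* **Interocular difference maps** — fellow-eye density maps rescaled to a
  common grid, the left eye mirrored to matching orientation, peaks
  aligned, signed and absolute differences over the overlap.
* **The symmetry statistics battery** — Shapiro-Wilk-gated paired t /
  Wilcoxon tests, Bland-Altman bias and limits of agreement with 95% CIs,
  Lin's concordance correlation, coefficient of variation of absolute
  differences, density-regularity correlation, sex subgroup analyses, and
  the smallest detectable paired difference from the noncentral-t power
  relation.
* **A synthetic fovea generator** — graded jittered triangular lattices
  under an anisotropic Gaussian density surface, with fellow-eye pairs and
  cohorts of programmable asymmetry, so the whole pipeline is testable with
  known ground truth.

## Worked example

Generate a synthetic fellow-eye pair with a +10,000 cones/mm^2 left-eye
peak offset and run the full per-subject analysis:

```r
library(foveamosaic)

spec <- synthetic_fovea_spec(peak_density = 150000,
                             falloff_sigma_x = 52, falloff_sigma_y = 42,
                             seed = 3)
pair <- generate_eye_pair(spec, delta_peak = 10000,
                          seed_od = 11, seed_os = 12)
rep <- run_subject(od = pair$od, os = pair$os,
                   control = map_control(map_scale = 2), sex = "F")
print(rep)
#> subject_report synthetic (F): eyes OD+OS
#>   OD: peak 140048 /mm^2, ICD 2.920 um, VCAR 7.55, roundness 0.813, area 0.002864 mm^2
#>   OS: peak 150034 /mm^2, ICD 2.829 um, VCAR 7.73, roundness 0.810, area 0.002902 mm^2
#>   interocular mean |OD-OS| density: 2264 /mm^2
```

Reading: the right eye peaks at ~140,000 cones/mm^2 and the left at
~150,000 — the programmed 10,000 offset recovered within a fraction of a
percent; cones at the left peak are correspondingly more tightly spaced
(ICD 2.83 vs 2.92 um). Both mosaics are similarly regular (VCAR ~7.6), and
the five isodensity contours are mildly elongated (roundness ~0.81,
reflecting the 42/52 sigma ratio of the programmed density surface).

Real data enter through `read_cone_coords()` (two-column x,y CSV per eye,
pixels or um) with the scale either given directly or via
`compute_linear_scale(scale_parameters(...))`; `run_cohort()` aggregates
subjects into the tidy metric table and runs the statistics battery per
metric.

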