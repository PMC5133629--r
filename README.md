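# topomorph

Time-lapse cell-shape morphometry and alignment analysis for
nanotopography experiments.

## The problem

Substrate nanotopography steers stem-cell shape and, through shape,
differentiation: mesenchymal stem cells cultured on aligned fibrous
nanostructures elongate and co-orient with the fibres, while random
nanostructures support small, round cells. Quantifying this requires
tracking population-level shape statistics over weeks of fluorescent
time-lapse imaging — thousands of frames across conditions, replicates and
fields of view — plus a way to ask *when* two conditions first become
morphologically distinguishable, and how the morphological changes line up
with gene expression.

`topomorph` implements that analysis as a tested, reusable R pipeline:

- **synthetic data** — a ground-truthed generator emulating a multi-week
  acquisition (three-phase imaging cadence, four conditions, replicates ×
  fields of view): cells start round, spread with saturating kinetics, and
  carry axial orientations drawn from a von Mises distribution on doubled
  angles; frames are rendered with PSF blur and photon-like noise alongside
  exact label masks and analytic shape records.
- **segmentation** — transparent threshold-based segmentation (Gaussian
  smooth → Otsu/fixed threshold → fill holes → size filter → connected
  components), with IoU-based validation against ground truth.
- **shape metrics** — per-object area *A*, contour perimeter *P*,
  circularity `4πA/P²` (1 for a circle, → 0 with increasing elongation),
  major/minor axis and orientation from the moment-equivalent ellipse
  (minimal enclosing ellipse available as an alternative).
- **alignment** — population orientation spectra by summing 2D-FFT power
  per angular bin over [0°, 180°), combined across fields of view,
  normalized, and stacked into a time × angle surface.
- **divergence statistics** — per-timepoint two-group F-tests
  (ANOVA form, `F = t²`; variance-ratio form optional) between condition
  pairs for each metric, and the first hour at which a metric diverges
  (`p < α` persistently), tabulated per metric × condition pair.
- **ΔΔCT expression** — relative qPCR quantification with housekeeping
  normalization (arithmetic mean of housekeeping CTs), calibrator
  conditions, fold change `2^(−ΔΔCT)`, log₂/log₁₀ reporting, and unpaired
  two-sample Student's t-tests on ΔCT values.

## Worked example

Simulate one aligned-substrate field of view 48 h after seeding, measure
it, and quantify its alignment:

```r
library(topomorph)

p <- default_conditions()$aligned          # mu = 90 deg, kappa = 8
pop <- sample_population(p, fov_um = c(1024, 1024), rng_seed = 42)
pop <- grow_population(pop, t_h = 48, p)
fr <- render_frame(pop, frame_geometry(512, 512, 2), noise = p$noise,
                   rng_seed = 43)

shapes <- measure_objects(segment_frame(fr), pixel_size_um = 2)
round(colMeans(shapes[, c("area_um2", "circularity", "major_axis_um",
                          "minor_axis_um")]), 2)
#>      area_um2   circularity major_axis_um minor_axis_um
#>       3254.67          0.54        128.76         32.11

spec <- combine_and_normalize(angular_power_sum(fr))
spec$angles_deg[which.max(spec$magnitude)]
#> [1] 90
```

By 48 h the cells have spread to ~3250 µm², lost most of their initial
circularity (0.54, against 1 for the round cells at seeding) and elongated
to a ~4:1 axis ratio; the FFT orientation spectrum peaks at 90°, the
orientation the population was generated at. Gene-expression analysis works
from a plain Ct table (a synthetic example table ships with the package):

```r
ct <- read_table_csv(system.file("extdata", "synthetic_ct_myogenic.csv",
                                 package = "topomorph"),
                     required = c("sample_id", "condition", "gene",
                                  "ct_value", "replicate"))
expr <- ddct_analysis(ct, housekeeping = c("B2M", "RPL13A"),
                      calibrator = "reference", log_base = 10)
subset(expr, gene == "PAX7",
       select = c(condition, fold_change, log_fold, p_value))
#>   condition fold_change   log_fold      p_value
#> 1   aligned   2.6549168  0.4240509 0.0003246326
#> 2      flat   0.6967276 -0.1569370 0.0385823642
#> 3    random   2.1425566  0.3309323 0.0008768350
```

The full pipeline — simulate → segment → measure → align → diverge
(→ ΔΔCT) — runs from one config:

```r
run_pipeline(demo_config(seed = 1), out_dir = "demo_out")
```

writing frames, masks, `shapes.csv`, `spectra.csv`, per-condition
time-angle surfaces, a divergence-hour table (`table1.csv`, metric rows ×
condition-pair columns, `NA` = never diverges) and a provenance log. A thin
command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "topomorph")`.

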