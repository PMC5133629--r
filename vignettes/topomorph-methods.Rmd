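---
title: "Models and methods behind topomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind topomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomorph)
```

`topomorph` quantifies how substrate nanotopography shapes a stem-cell
population's morphology over multi-week fluorescent time-lapse experiments.
This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic validation shows.

## The synthetic experiment

No imaging data accompany the analysis design this package implements, so
the package's first-class citizen is a generator that emulates the
acquisition: four conditions (flat glass, flat glass in osteogenic medium,
random nanotopography, aligned nanotopography), run in duplicate with four
fields of view each, imaged on a three-phase cadence — every 10 min for the
first 6 h, every 15 min to 96 h, then hourly to 504 h (21 days). The phase
grid is enumerated per phase as `start + k·interval` with boundaries counted
once, giving 805 timestamps with no floating-point drift; `make_schedule()`
rejects gapped, overlapping or non-divisible phases.

**Orientations.** Cell orientation is axial data (θ and θ+180° are the same
state), so orientations are drawn from a von Mises distribution on *doubled*
angles: φ ~ VM(2μ, κ), θ = φ/2. This is the standard generative model for
axial data; κ = 0 gives uniform orientations (the flat, flat-osteo and
random conditions), while the aligned condition uses μ = 90°, κ = 8,
matching the near-vertical fibre orientation and tight co-alignment the
aligned substrate induces. The sampler is a vectorised Best–Fisher rejection
sampler, validated in the tests against an independent
rejection-from-uniform oracle at 10⁶ draws.

**Spreading kinetics.** Cells begin as round unattached discs (radius
10 µm, a typical suspended mesenchymal stem cell) and spread towards a
condition-specific plateau area and aspect ratio. Only the qualitative
trend — rise over the first day, then plateau — is constrained by the
biology, so both quantities follow the simplest monotone saturating form,
an exponential approach `x(t) = x₀ + (x∞ − x₀)(1 − e^(−t/τ))` with a shared
time constant τ = 6 h, which puts ~98 % of spreading inside the first day.
Default plateaus encode the observed ordering between conditions: aligned
cells large and strongly elongated (3200 µm², 4:1), flat-osteo the largest
and most isotropic (3800 µm², 1.5:1 — spreading in all directions, hence
also the largest minor axis), flat intermediate (2200 µm², 2:1), random the
smallest and roundest (1400 µm², 1.6:1). These are generative stand-ins,
not measurements; every analysis result on synthetic data must be read
relative to them. Per-cell lognormal multipliers (CV 10 % on area, 5 % on
aspect ratio) provide population heterogeneity that persists over time.

**Rendering.** Each cell is a filled uniform-intensity ellipse, blurred
with a Gaussian PSF (σ = 1 px), over a constant background (5 % of range)
with signal-dependent Gaussian noise (scale 0.02·√intensity) — an SNR
regime comparable to a healthy fluorescent-reporter acquisition. Labelled
cells are deliberately sparse (default 12 per field of view), mirroring the
dilution of reporter-expressing cells used experimentally to avoid
overlaps; placement is rejection sampling with a minimum centroid spacing
of twice the plateau semi-major axis, the worst-case non-overlap bound for
arbitrarily oriented ellipses. A retry budget turns impossible densities
into an explicit error. Frames and truth masks are 16-bit single-channel
TIFFs with a manifest CSV; everything is a deterministic function of the
seed.

What the generator does *not* emulate: cell texture, motility, division,
death, touching/overlapping cells, uneven illumination, photobleaching and
focus drift. Passing tests therefore demonstrate the correctness of the
measurement and statistics machinery, not robustness to those real-data
pathologies — segmentation on real micrographs will need its parameters
revisited per dataset.

## Segmentation

The segmentation stage is intentionally boring and fully declared: Gaussian
smooth (σ = 1 px) → global Otsu threshold → fill holes → drop objects below
`min_area_px` → optionally drop border-touching objects →
connected-component labelling (8-connectivity by default, recorded in the
output). A fixed threshold is available for determinism-sensitive tests.
There is no declumping or watershed: the acquisition design avoids touching
labelled cells by dilution, so merged objects are simply rare large
objects. A constant frame under Otsu yields an empty mask with a
`degenerate` flag rather than an error. Validation is greedy one-to-one
matching by pixel overlap with per-pair IoU; on the non-overlapping
synthetic suite the pipeline holds mean IoU ≥ 0.8 with exact object
counts, the package's stand-in for manual-versus-automated agreement.

## Shape metrics

Per object: area A (pixel count × pixel area), perimeter P, circularity
`4πA/P²`, and the axes/orientation of a fitted ellipse.

**Perimeter.** Circularity's denominator is the step that decides whether a
digitised circle scores 1, so the estimator matters. A naive chain-code
length overestimates smooth boundaries by ~5 % (circularity ≈ 0.90 for a
circle); a crack-boundary count overestimates by ~27 %. The package traces
the boundary by Moore-neighbour following and applies the
Vossepoel–Smeulders corrected step weights (0.980 per axial step, 1.406 per
diagonal step, −0.091 per direction change), then adds π: the chain passes
through boundary pixel *centres*, half a pixel inside the true outline, and
offsetting any simple closed curve outward by half a pixel adds 2π·½ to its
length. The combination is accurate to < 1 % on circles of radius ≥ 50 px
and ~0.5 % on 4:1 ellipses, while keeping a 20 px square within 5 % of its
true 80 px perimeter and giving a single pixel the perimeter π of its
offset disc. Raw circularity can still exceed 1 by a few parts per thousand
on small circles, so the reported value is clamped at 1 with the raw value
kept alongside.

**Ellipse axes.** Two definitions ship. The default is the
moment-equivalent ellipse — the ellipse with the same normalized second
central moments as the pixel set, axis lengths `4√λ` of the covariance
eigenvalues — which is what standard region-measurement software computes
and therefore what population statistics should be built on. The
alternative is the literal "smallest ellipse that completely encloses the
cell": the minimum-volume enclosing ellipse of the convex hull of the pixel
corners, via Khachiyan's algorithm (tolerance 10⁻⁴). The two agree within a
few percent on convex rasters (the enclosing ellipse is systematically
~half a pixel larger per side); which was intended by a given upstream
dataset cannot generally be recovered, so each record carries its method.
Collinear pixel sets get a minor axis floored at 1 px and a degeneracy
flag. Orientation is measured counter-clockwise from the image +x (column)
axis, range [0°, 180°), consistently across the generator, the metrics and
the FFT module; the round trip generate → render → segment → measure
recovers orientations within ±2°.

## Alignment from the 2D FFT

Features elongated at angle θ concentrate Fourier power along the
perpendicular spectral direction. `angular_power_sum()` mean-subtracts the
frame, applies a Hann window (without it, frame edges inject a spurious
cross at 0°/90°), computes |FFT|², excludes DC, and sums power into angular
bins (default 180 × 1°) after rotating spectral angles by 90° so the
reported angle is the real-space elongation angle. Only a radial band of
spatial frequencies is integrated — by default from 4 spectral pixels up to
half Nyquist, excluding field-of-view-scale structure below and pixel noise
above; the band is configurable, and is a declared choice rather than a
derived one. Spectra from the fields of view of one condition/timepoint are
summed bin-wise and normalized to unit total (making the measure invariant
to total fluorescence), then stacked over the schedule into a time × angle
surface whose per-row argmax is the peak trace. For the aligned condition
the trace sits at 90° ± 1 bin throughout; for uniform orientations and for
day-0 round cells the spectrum is flat. "Flat" is judged against a
Monte-Carlo null: single 1°-binned spectra of sparse fields are intrinsically
spiky (max/median ≈ 4–5 even for isotropic fields), so the tests calibrate
the flatness statistic on uniform-orientation renders and require isotropic
conditions to fall inside, and the aligned condition far outside, that band.

## Divergence statistics

Objects are pooled per condition × timestamp across replicates and fields
of view (population statistics, not a nested model — matching how such
acquisitions are conventionally analysed). For a condition pair and metric,
each timepoint gets a two-group F-test. "F-test" between two measured
distributions is ambiguous, so both readings ship: the default is the
one-way two-group ANOVA F with df (1, nₐ+n_b−2) — a location test,
identical to the squared pooled-variance t (the identity `F = t²` is
enforced in tests against `t.test`) — and a variance-ratio F (`var.test`)
is an explicit alternative mode, recorded in every result. The divergence
hour is the first timestamp where `p < α` (default α = 0.05) persists for
`persistence_k` consecutive timepoints; `k = 1` reproduces a plain
first-rejection rule at the grid's sub-hour resolution, larger `k` guards
against isolated false positives. No multiple-testing correction is applied
across the ~800 timepoints by default — the first-rejection reading of the
rule — but a `p.adjust` mode (e.g. Holm) is available. Simulation checks:
type-I rate 0.05 ± 0.02 under the null; an injected 1-SD mean shift at hour
12 (n = 200/timepoint) is recovered within two grid steps (median over 50
seeds); identically generated conditions diverge in < 5 % of seeds at
α = 0.05, k = 3. Mean-ratio trajectories (mean A / mean B per timepoint,
summarised by median |log ratio|) provide the complementary
effect-size view; with the default generator parameters the pairs furthest
from unity always involve the random condition, the smallest-area
phenotype.

## ΔΔCT expression analysis

ΔCT = CT_target − CT_housekeeping per replicate, with several housekeeping
genes combined by the arithmetic mean of their CTs (equivalent to the
geometric mean of expression levels). ΔΔCT subtracts the calibrator's mean
ΔCT; fold change is `2^(−ΔΔCT)` with no amplification-efficiency
correction. Per-replicate folds are summarised by their *geometric* mean,
i.e. `2^(−mean ΔΔCT)`: averaging on the log scale is the natural choice for
ratios and is the only summary under which a condition calibrated against
itself reports fold 1 exactly and `log₂(fold) = −ΔΔCT` holds as an
identity. Group comparisons are unpaired two-sample pooled-variance
Student's t-tests on ΔCT values (never on folds), two-sided, with the
degenerate zero-variance cases handled explicitly. Calibrators are just
conditions: a flat-substrate control and a reference-cDNA pool are handled
identically by naming them as the calibrator.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → segment → measure → align → diverge
(→ ΔΔCT when a Ct table is configured), writing CSV artifacts (UTF-8,
comma-separated, '.' decimal, strict schema validation with line-numbered
errors) plus a log carrying the seed, a config hash and per-stage timings.
Two runs with one config are hash-identical.

The shipped demo configuration is a compressed stand-in for the full
design: the four conditions at 2 replicates × 4 fields of view, a 48-hour
two-phase schedule (9 timepoints), 256 px fields at 2 µm/px with 8 labelled
cells each — 288 frames, about half a minute end to end. The test-suite
simulations are sized similarly (fields of 192–512 px, tens of seeds where
distributions are checked); these sizes were chosen so the whole validation
suite runs comfortably on a laptop while keeping every statistical check
adequately powered, and they are stated here as the package's reference
problem sizes. The full 805-timestamp, 1024 px design runs through exactly
the same code paths, only longer.

## Known limitations

- Per-frame population statistics only: no tracking, so no per-cell
  velocity, lineage or shape-trajectory statistics.
- The segmentation stage assumes sparse, non-touching labelled cells; dense
  cultures need declumping that is out of scope here.
- The moment/enclosing ellipse ambiguity is resolved by configuration, not
  inference; cross-dataset comparisons should fix one method.
- The FFT radial band and normalization are declared defaults; absolute
  spectrum shapes are comparable only within one configuration.
- Divergence hours inherit the acquisition grid's resolution and, with
  `k = 1`, the multiplicity behaviour of a first-rejection rule: under the
  null, some metric/pair will eventually reject by chance over ~800
  timepoints. The persistence and Holm options exist for exactly that
  reason.
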