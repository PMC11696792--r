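---
title: "Quantifying single and collective cell migration with cellmig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single and collective cell migration with cellmig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmig)
```

cellmig implements the quantitative layer of a cell-migration study as a
set of testable components: persistence fitting of single-cell
trajectories, particle image velocimetry (PIV) of wound-healing monolayer
movies, space-time maps of speed and order parameter, fluorescence
line-scan quantification, the bookkeeping of an AlphaFold2-based
fragment screen, qPCR isoform fractions and interaction-proteomics
specificity filtering. Every stage can be exercised on seeded synthetic
data with recorded ground truth, so correctness is established by
parameter recovery rather than by eye.

## Migration persistence of single cells

A cell tracked at a fixed frame interval (10 min by default, matching the
usual videomicroscopy cadence) yields step vectors between consecutive
positions. The direction autocorrelation at lag $t$ is the mean cosine of
the angle between step vectors separated by $t$; the persistence of each
cell is summarised by fitting

$$y(t) = (1 - b)\,e^{-t/a} + b,$$

where $a > 0$ (minutes) is the decay constant of the directional memory
and $b \in [-1, 1]$ is the long-time plateau. The model passes through
$y(0) = 1$ exactly; lag 0 is included in the fit to anchor that value.
Fitting uses bounded Levenberg–Marquardt least squares with a
deterministic restart schedule (up to 20 restarts; initial values
$a_0 = $ lag span / 4, $b_0 = $ mean of the last lag quartile). The
maximum lag defaults to half the track length, the usual compromise
between lag coverage and tail noise. Pairs that involve a zero-length
step are dropped, since a zero step has no direction. A curve that sits
within $10^{-6}$ of 1 everywhere is the plateau-only limit and is
reported as $b = 1$, $a = \infty$, converged.

Two estimator routes are provided. `fit_cohort(method = "per_cell")`
fits each cell separately, matching per-cell readouts; at typical track
lengths (about 40 frames) the per-cell plateau carries a small negative
skew (about $-0.07$ in the median at $\tau = 60$ min, 6.5 h tracks),
because negative tail noise can only be absorbed by $b$ while positive
tail noise can also be absorbed by a larger $a$.
`fit_cohort(method = "mean_curve")` fits the cohort's pointwise mean
curve and is nearly unbiased for both parameters (median $a$ within 1%
of truth, median $b$ within 0.005 at the default study scale of 60 cells).
Both are reported by the acceptance machinery; users comparing
conditions should use the same route on both sides.

Group comparison (`compare_persistence`) uses a two-sided, seeded
bootstrap (10,000 resamples) of the difference in group means of the
fitted plateau $b$ (primary) and decay constant $a$ (secondary). The
resampling stream of each group is derived from the group's own sorted
values, which makes the result exactly invariant under a swap of group
labels. The published analyses cite custom comparison code whose exact
statistic is not restated here; the bootstrap is a documented,
defensible substitute, not a reproduction of that code.

### The track generator as its own oracle

`gen_tracks` simulates a persistent random walk with a heading that
undergoes discrete-time rotational diffusion:
$\Delta\theta \sim N(0,\, 2\,\Delta t/\tau)$ per frame, chosen so that the
direction autocorrelation of the unbiased walk is exactly
$e^{-t/\tau}$ — a closed form against which the whole
autocorrelation-plus-fit chain is checked. Step speeds are drawn per
step from a Gaussian truncated at zero (defaults 0.5 ± 0.15 µm/min),
decoupling speed from persistence as in the separate speed/persistence
readouts of migration assays. A drift `bias` in $[0, 1)$ mixes a fixed
unit vector into each step direction; the induced plateau has no tidy
closed form, so the mapping is measured once by long simulation
(`bias_plateau`; e.g. bias 0.5 gives a plateau near 0.40, bias 0.25
near 0.03) and treated as the generator's ground truth.

## PIV of wound-healing movies

`piv_pair` estimates the displacement field between consecutive frames
with 32-px interrogation windows at 0.75 overlap (grid step 8 px), the
standard monolayer settings. Windows are mean-subtracted and correlated
by zero-padded FFT cross-correlation; the correlation plane is
normalized by the per-shift overlap count, which removes the classic
loss-of-pairs bias toward zero displacement. The integer peak is
searched within a quarter window (the one-quarter rule; configurable via
`search_px`) and refined to subpixel precision with a three-point
Gaussian fit per axis, falling back to a parabolic fit when a
neighbouring correlation value is non-positive. Peak quality is the
ratio of the highest to the second-highest peak outside the main peak's
3×3 neighbourhood. Flat (zero-variance) windows — typically the
cell-free wound — are flagged invalid rather than propagating NaN.

Post-processing follows the published order: spurious vectors are
filtered on amplitude (outside mean ± 3 SD of the field's magnitudes),
replaced by the distance-weighted mean of their valid 8-neighbourhood
(iterated outward until filled), and the fields are then averaged with a
4-frame trailing time window (40 min at the default cadence). The time
axis of averaged fields is labelled by the window's first frame so the
map starts at insert lifting. A field left with more than 50% invalid
vectors is rejected as unusable. Velocities are reported in µm/h
(`displacement_px · pixel_um · 60 / dt_min`).

On synthetic texture the implementation recovers planted integer shifts
within 0.05 px and subpixel shifts within 0.1 px in the mean, with RMS
error below 0.2 px at 5% additive noise. A single-pass fixed window is
used deliberately — no multi-pass deformation — matching the stated
window configuration; displacements beyond a quarter window should be
handled by lowering the frame interval rather than by trusting larger
search radii.

## Wound geometry, order parameter and space-time maps

The wound is segmented as the largest connected low-texture region
touching the wound-side border: the local intensity SD (disk radius 8
px, replicated boundary) is thresholded with Otsu's method, and the
candidate must be clearly smoother than the remaining frame (mean local
SD below half the outside value). Per column, the wound depth gives the
boundary coordinate; its mean across columns, tracked over frames, gives
leading-edge progression in µm. Classification is exact away from one
disk radius of the true boundary; the mixing zone makes the recovered
edge sit 2–4 px inside the true one, a constant offset that cancels in
progression slopes (edge speed is recovered within 5% on synthetic
movies).

The order parameter of a displacement vector is the cosine of its angle
to the unit vector pointing perpendicular to the wound axis, toward the
wound: 1 for coordinated advance, 0 for flow along the edge. It is the
per-vector cosine as described in the study's results; a
neighbourhood-averaged variant can be obtained by averaging the returned
matrix. Zero-magnitude vectors are excluded as directionless.

`build_heatmap` bins every valid vector by its distance from the
instantaneous front edge (recomputed each frame, not the initial edge —
a config choice matching maps that keep "the front edge at the top")
and by time. Band width defaults to the PIV grid step in µm so no
interior band is empty. Within a movie, values are averaged per
(band, time) cell; across movies, per-movie cell means are averaged, as
in figures that average several fields of view per replicate. Empty
cells are NA with a contributing count of zero; counts are conserved
(each valid monolayer-side vector lands in exactly one cell).

The movie generator advects a smooth random texture (grain 2 px,
intensities in [0, 1], 16-bit TIFF export) toward a flat wound with the
field $v(d) = v_0 e^{-d/\lambda}$ of the edge distance $d$, by backward
bilinear warping plus per-frame regenerated noise; the edge advances at
$v(0)$. Defaults ($v_0 = 20$ µm/h, $\lambda = 50$ µm, pixel 0.7422 µm,
10-min frames) give edge motion of about 0.45 px/frame, typical of
epithelial wound closure. The full chain — segmentation, PIV,
validation, temporal averaging, heat map — recovers the planted profile
within 10% over the first five populated distance bands.

## Fluorescence line scans and edge enrichment

`extract_profile` samples a user-drawn line every pixel with bilinear
interpolation, averaging `width_px` perpendicular samples. Registration
shifts each profile so the maximum of a reference channel (e.g.
phalloidin or cortactin) sits at distance 0 ("edge" mode; "junction"
mode keeps a user-annotated zero), then resamples all profiles onto a
common grid, by default spanning −2.5 to +2.5 µm. Profiles whose
reference maximum falls on a scan end, or whose reference channel is
flat, are rejected with a reason. Averaging normalizes each profile per
channel to max = 100% by default ("percent of max"; a percent-of-sum
option is provided — it weights broad and narrow peaks differently), so
the registered landmark has mean 100% and SEM 0 by construction, and
off-landmark points carry the biological spread. The registration
landmark and normalization denominator of the original figures are not
stated; both are explicit config choices here.

The edge-enrichment ratio divides the mean intensity of an edge band by
that of an equal-area band beneath the membrane (areas within 10%,
non-overlapping), after optional constant background subtraction. The
ratio is invariant to multiplying the image by a positive constant, but
not to additive offsets unless the background is subtracted — both
behaviours are asserted in the tests.

## Fragment-screen bookkeeping

The structure-prediction screen itself (AlphaFold2/ColabFold, MMseqs2,
MAFFT, hhfilter) is out of scope; the package implements the
surrounding contracts so a screen can be driven, mocked and audited:

* `make_fragments` places $n$ overlapping windows of ~100 residues with
  fragment $i$ starting at $\mathrm{round}((i-1)(L - 100)/(n-1)) + 1$;
  for a 1046-residue bait and $n = 15$ this gives first fragment 1–100,
  last 947–1046 and overlaps of 32–33 residues. When $n$ is omitted,
  the smallest count with overlap ≥ 20 is used. Explicit domain
  delimitations are accepted verbatim (validated for increasing,
  overlapping bounds; a warning if they do not reach the termini).
* `filter_msa` applies the identity/coverage contract (defaults
  qid 25%, cov 50%), removes exact duplicates (the `id = 100` setting),
  and keeps one sequence per species — the highest identity to the
  query. Coverage is the row's non-gap fraction over query columns;
  identity is matches over query columns where both are non-gap. These
  definitions are this package's documented reading of the hhfilter
  parameters, which the source text does not restate.
* `pair_msas` builds the mixed co-alignment: queries concatenated first,
  one concatenated row per common species, and single-sided rows padded
  with gaps on the partner block; row and width accounting is exact and
  asserted.
* `aggregate_scores` stores all scores on [0, 1] (pLDDT divided by 100),
  computes per-model confidence $0.2\,\mathrm{pTM} + 0.8\,\mathrm{ipTM}$,
  the mean ipTM over up to five models, and the best per-model
  confidence. `screen_candidates` ranks by average ipTM (the published
  initial ranking) and selects strictly above 0.65 on best confidence by
  default; whether the published selection used best or average
  confidence is not explicit, so the selector column is configurable and
  both aggregates are always reported. The predictor is an interface:
  `mock_predictor` replays a fixture table; real runs would supply a
  function that shells out to an external pipeline.

## qPCR fractions and partner filtering

Isoform fractions use $2^{-\Delta C_t}$ with
$\Delta C_t = C_t^{\mathrm{isoform}} - C_t^{\mathrm{total}}$ from the
same sample, replicates averaged on the $C_t$ scale first. Fractions of
overlapping amplicons are reported per amplicon and not forced to sum
to 1; `isoform_shares` provides the post-hoc proportioning used for
"respective abundance" displays.

The partner filter retains proteins detected (LFQ intensity > 0, the
MaxQuant zero-imputation convention — no magnitude threshold is applied)
in at least 2 of 3 bait replicates, in no control replicate, with at
least 2 razor + unique peptides, sorted by mean bait intensity. The
synthetic LFQ generator plants true partners that satisfy all three
rules and decoys that each violate exactly one, so recovery must be
exact, and a brute-force row-by-row oracle cross-checks the filter on
random tables.

## Numerical and design notes

* All generators are seeded and bit-reproducible; operations use no
  hidden RNG (the fit's restart schedule is deterministic).
* Coordinates are image coordinates throughout PIV and wound analysis:
  origin top-left, x along columns, y increasing downward; the
  wound-ward direction handles the sign flip once.
* The strict `> 0.65` selection respects the printed "above"; the test
  suite pins the boundary (0.66 in, 0.65 out).
* Problem sizes in the tests and acceptance script (e.g. 100–200
  simulated cohorts of 60 cells, 320×160-px movies of 10 frames) were
  chosen as the smallest sizes at which the Monte-Carlo tolerances of
  the recovery checks are comfortably resolved.
* What passing tests show: recovery of planted parameters under the
  generators' assumptions — uniform texture advected by a smooth field,
  Gaussian line-scan peaks, Gaussian heading increments. Real data adds
  cell divisions and collisions, texture evolution, uneven illumination
  and segmentation ambiguity that these generators deliberately do not
  model; results on real movies should be sanity-checked against the
  movie (e.g. peak-quality maps, fraction of filled vectors).

## Limitations

Single-pass PIV cannot resolve displacements beyond a quarter window;
tracks with gaps are rejected rather than split; wound segmentation
assumes a single straight-ish wound touching one image border; the
fragment screen never runs a predictor itself. The bootstrap group
comparison is a documented substitute for unpublished custom code, and
per-cell plateau estimates carry the negative skew quantified above.
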