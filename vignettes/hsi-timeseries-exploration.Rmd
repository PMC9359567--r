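---
title: "Methods: exploring hyperspectral image time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exploring hyperspectral image time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsitime)
```

## The problem

A hyperspectral imager records a full radiance spectrum per pixel, so one
sample at one time point is a cube `H[y, x, s]` (here nominally 380–750 nm).
When the same organisms are imaged repeatedly around a stressor exposure
(before, directly after, two and six weeks after), physiological responses
can appear as *local* spectral changes: a subset of pixels whose spectra
lose weight in the blue and gain in the red — a red shift — while
whole-sample mean spectra barely move. Two properties of such data shape
everything in this package:

1. Acquisitions at different time points are **not spatially registered**.
   A spatial region drawn in one image has no automatic counterpart in
   another; any cross-time comparison must go through either user-drawn
   per-time-point regions or a spatial-hypothesis-free route.
2. The interesting signal is a **shape** change of the spectrum, not an
   amplitude change. Illumination and viewing geometry scale whole spectra,
   so comparisons operate on l1-normalized spectra
   `H̃[s] = H[s] / Σ_s′ |H[s′]|` (absolute sum 1).

## Data model and conventions

Pixels use 0-based `(x, y)` = (column, row) coordinates; arrays are stored
`(y, x, s)`. The four time points are ordered by a fixed enum
`T0 < T0.5 < T1 < T2` — never by string sort, which "T0.5" breaks. Each cube
carries a boolean coral mask; all analysis is restricted to mask-true
pixels, and background is rendered black. Cubes are persisted one HDF5 file
per sample per time point (`/values` as float32 in C order, `/wavelengths`,
`/mask`, metadata as root attributes), so any HDF5 reader sees the
documented h×w×S layout. Multi-sample scans are split into per-sample cubes
by polygon annotations; a pixel belongs to a polygon iff its center
`(x + 0.5, y + 0.5)` lies inside (crossing-number rule), which makes
axis-aligned rectangles behave as half-open boxes and keeps rasterization
deterministic.

Degenerate all-zero spectra (dead pixels) cannot be l1-normalized; they are
excluded from aggregation and embeddings with a warning rather than failing
a whole cube.

## Spectral, image and embedding domains

*Agglomeration spectra* summarize a pixel set channel-wise with mean, max,
min or median (median over an even count is the midpoint of the central
pair). With normalization requested, each pixel spectrum is normalized
*before* aggregation, matching the per-spectrum definition of the
normalization; the flag exists because aggregate-then-normalize is a
defensible alternative, but normalize-first is the default and what the
embedding uses.

*Pseudo images* collapse the spectral axis per pixel (mean/max/min/median or
a single nearest channel). Display scaling maps the masked minimum and
maximum affinely to [0, 255] (a constant image maps to 0 by convention),
with round-half-up for platform determinism; scaling statistics deliberately
ignore background pixels, which would otherwise dominate the dynamic range.
Brightness multiplies and clips at 255. The pseudocolor table is a fixed
256-entry spectral-style lookup shipped with the package — deterministic and
injective across the 256 grey levels; no claim is made of color identity
with any particular plotting library's colormap.

*Embeddings* stack the l1-normalized spectra of every masked pixel from all
four time points of one sample — per sample, not across samples, so each
display compares a sample with itself over time — and map them to 2-D with
UMAP (euclidean or cosine) or t-SNE (euclidean only; requesting cosine
raises an unsupported-combination error rather than silently substituting).
Row order is time-point order then y-major pixel order, and the
`EmbeddingResult` records the bijection row ↔ `(time point, x, y)` plus
method, metric, seed and parameters, making every downstream selection
reproducible. Defaults are UMAP `n_neighbors = 15`, `min_dist = 0.1`, t-SNE
`perplexity = 30`, seed 42; UMAP runs single-threaded so equal seeds give
bit-identical coordinates. Because embeddings are the expensive step, they
are persisted to HDF5 with a schema version and validated on load. An
optional seeded uniform subsampling (`params$subsample_n`) exists for very
large cubes but is off by default.

The *PCA biplot* of an embedding selection uses standard PCA
(`stats::prcomp`): scores are centered data projected on the top two axes,
loadings are those axes with one arrow per wavelength, colored by an
approximate wavelength-to-RGB map so arrows read as spectral bands. Rank-1
data flag the second component as degenerate instead of erroring — a
selection of near-identical spectra is a legitimate user action.

## Link and brush

A `Selection` is a set of `(time point, x, y)` references with provenance
and a visible-time-point set. Image polygons bind to exactly one time point
(no registration exists); embedding shapes select rows and therefore pixels
at any visible time point; hiding time points filters projections without
touching the pixel set, and is an involution. Projections materialize a
selection as per-time-point highlight masks, agglomerated spectra, and
embedding rows. Union/intersection/difference are provided so the workflows
can be scripted; when selections would conflict interactively, the package's
convention is that a new selection replaces the active one unless explicitly
composed.

## Change quantification

`crossing_wavelengths()` reports each sign change of `a − b` between
adjacent channels at the linearly interpolated wavelength — the curves are
piecewise linear between channels, so sub-channel localization is the
natural reading of a single reported crossing wavelength. Exact zeros at a
channel report that channel once; zero plateaus report their boundary
wavelengths; identical spectra report nothing.

`band_shift_index()` turns "lowered blue, elevated red" into a scalar:
`(mean_b(red) − mean_a(red)) − (mean_b(blue) − mean_a(blue))` on
l1-normalized spectra, positive for a red shift from `a` to `b`,
antisymmetric in its arguments. The index definition is this package's own
quantification of that qualitative description. Default bands are
400–500 nm (blue) and 600–700 nm (red): conventional color bands that sit
inside the instrument's 380–750 nm range with margin on both sides;
configurable per call.

`detect_timepoint_exclusive_regions()` automates the manual gating step of
outlining embedding regions populated by one time point only. Restricted to
the two compared time points, each row's `k` nearest neighbors (euclidean in
embedding coordinates) vote: rows whose same-time-point fraction reaches the
purity threshold are returned. In a well-mixed stationary embedding the
expected fraction is ≈ 0.5, so `k = 15`, `purity = 0.9` (defaults) demand
strong local exclusivity; this k-NN statistic was chosen as the simplest
faithful automation (a grid-density alternative was considered and not
pursued). Detection is monotone in purity.

## Observer ratings

Change ratings `r ∈ {1..5}` per sample/time comparison are human input, not
computed — the package aggregates them. `average_change_rating()` is the
arithmetic mean; `star_glyph_table()` arranges per-condition matrices of
mean ratings (coral × comparison) for radial plotting. For inter-observer
agreement two estimators are exposed, because a single summary SD can be
computed either way and the choice matters: the default is the SD of all
pairwise between-observer differences over jointly rated items (a constant
offset between two observers then contributes nothing), the alternative is
the mean of per-item across-observer SDs (an offset contributes fully).

## The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which everything else is validated. Defaults: 64×64 pixels, 40 channels over
380–750 nm, an elliptical mask (≈ 2 000 coral pixels), shift fraction
p = 0.2, tilt magnitude δ = 0.1, multiplicative per-channel Gaussian noise
σ = 0.02, shift at T2 only. Choices and rationale:

- **Base templates**: smooth strictly positive spectra; white morph is
  broadband with a mild long-wavelength rise, orange adds a pigment hump at
  590 nm. They are invented templates, not measured reflectances.
- **Linear tilt as the canonical red shift**: shifted pixels' spectra are
  multiplied by `1 + τ(s)` with τ ramping from −δ to +δ across the axis.
  This is the simplest model that lowers blue, raises red, and — after
  l1 normalization — crosses the unshifted spectrum exactly once, at an
  analytically computable wavelength, giving `crossing_wavelengths()` a
  closed-form target. Positivity holds for δ < 1.
- **Multiplicative noise**: radiance scales with illumination, and relative
  noise keeps normalized shapes stable; σ = 0.02 makes the per-channel
  perturbation comparable to the tilt at mid-axis without drowning it —
  detectable but not trivial.
- **Persistent shifted set**: the shifted pixel subset is drawn once
  (seeded, exactly `round(p·|mask|)` pixels) and reused at every shifted
  time point, modeling a lasting local physiological response.
- **Wrong-mask fixture**: a stationary series whose T0 mask is dilated by a
  2-pixel disk into the flat-spectrum background, emulating an annotation
  error at a single time point. Its background pixels form
  time-point-exclusive embedding structure — the same signature the
  detection op flags for genuine change, which is exactly the documented
  failure mode of mask-dependent analysis.

What the generator does *not* emulate: illumination fields, water-column
attenuation, spatial texture and polyp morphology, registration jitter, or
dose–response relationships. Passing recovery tests on this model therefore
demonstrates that the machinery detects and localizes shape changes of the
configured kind and size; it does not certify sensitivity on real coral
radiance data, where no quantitative shift magnitude is established (reported
shifts are below human RGB perception).

## Workflows and problem sizes

The *morphology workflow* takes one user ROI per included time point
(unregistered images make this the user's responsibility), aggregates
normalized ROI spectra, and reports crossings and band shift of each later
time point against T0. The *embedding workflow* needs no spatial
hypothesis: embed, restrict to two time points, detect exclusive regions,
transfer the detected pixel coordinates to the other time point's cube
(coordinates, not registration — valid for the generator and near-aligned
rigs, and flagged `coordinate_transfer_approximate` in the report), then
quantify the change. A detected region covering at most 5% of the later
time point's pixels is treated as noise and reported as
`no_exclusive_regions` — this threshold defines the workflow's
false-positive flag. Reports are pure functions of inputs and seeds;
serialized reports are byte-identical across reruns.

Validation runs use the generator defaults (four cubes of 64×64×40, ten
seeds for recovery and ten for the false-positive control) — large enough
that the embedding has real cluster structure, small enough to iterate on
a laptop; unit tests use smaller cubes where the property under test does
not depend on size.

## Known limitations

- Coordinate transfer across time points assumes near-aligned acquisitions;
  with real inter-acquisition motion the transferred region is only a
  spatial approximation (the flag in the report exists for this reason).
- t-SNE is euclidean-only and not recommended for the cosine-style
  shape comparison; UMAP/cosine is the default for a reason.
- The detection statistic is purity-based and will flag *any*
  single-time-point structure, including artifacts such as the wrong-mask
  fixture — by design, but it means a detection is a hypothesis to inspect,
  not a verdict.
- The published per-observer rating tables behind the inter-observer
  agreement summary exist only as PDF supplements, so that value cannot be
  recomputed here; both candidate estimators are implemented and tested on
  synthetic tables instead.
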