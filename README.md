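# hsitime

Headless, scriptable exploration of **time series of hyperspectral images
(HSI)** of masked benthic samples — the setting is laboratory monitoring of
cold-water coral nubbins imaged at four time points (T0, T0.5, T1, T2) around
a particle-stressor exposure, but the machinery is generic.

A hyperspectral cube records a full radiance spectrum per pixel,
`H[y, x, s]` over `S` wavelengths (nominally 380–750 nm). Spectral change
over time — e.g. a *red shift*, lowered blue and elevated red values — is
often confined to small parts of a sample and invisible in whole-sample
averages. `hsitime` implements the three linked analysis domains that make
such local changes findable without a prior spatial hypothesis:

- **Image domain** — per-pixel spectral aggregates rendered as pseudo
  grey-value images (`mean`/`max`/`min`/`median` or a single channel),
  linearly scaled to [0, 255], with brightness and a fixed spectral
  pseudocolor lookup table.
- **Spectral domain** — agglomeration spectra (channel-wise mean, max, min,
  median) over arbitrary pixel sets, with optional per-pixel
  l1 normalization `H̃[s] = H[s] / Σ|H[s′]|` that removes amplitude and keeps
  spectral shape.
- **Embedding domain** — all masked, l1-normalized pixel spectra of a
  sample's four time points pooled and mapped to 2-D (UMAP with euclidean or
  cosine metric, or t-SNE), with an explicit bijection between embedding
  rows and `(time point, x, y)` pixel references.

Selections made in any domain (image polygon, embedding lasso/rectangle,
time-point filter) resolve to a canonical pixel set and project into the
other domains (*link and brush*). On top sit:

- `detect_timepoint_exclusive_regions()` — k-NN time-purity detection of
  embedding regions populated by only one of two compared time points;
- `crossing_wavelengths()` and `band_shift_index()` — where two spectra
  cross (linear interpolation between channels) and how much red-band gain
  minus blue-band gain separates them;
- `pca_biplot()` — PCA scores plus per-wavelength loading arrows for the
  spectra behind an embedding selection;
- observer change-rating aggregation (`average_change_rating()`,
  `inter_observer_sd()`, `star_glyph_table()`);
- a synthetic generator (`simulate_timeseries()`, `wrong_mask_fixture()`)
  producing coral-like cubes with known ground truth (a seeded subset of
  pixels whose spectra acquire a linear red-shifting tilt, or a T0 mask
  dilated into the background).

Cubes are stored one HDF5 file per sample per time point
(`/values` h×w×S float32, `/wavelengths`, `/mask`, metadata attributes);
multi-sample scans are split into per-sample cubes with polygon annotations
(`split_scan()`). A thin CLI lives at `inst/scripts/hsitime`.

## Worked example

Simulate a sample in which 20% of coral pixels acquire a 10% red-shifting
spectral tilt at T2, then let the embedding-driven workflow find them with
no spatial hint:

```r
library(hsitime)

cfg <- synthetic_config(seed = 7)      # 64x64, 40 channels, p = 0.2, tilt 0.1
sim <- simulate_timeseries(cfg)
sim$ts
#> <hsi_timeseries> sample 'synthetic-7' (control, 0 mg/L), 4 time points
#>   T0   64 x 64 px, 2056 masked
#>   T0.5 64 x 64 px, 2056 masked
#>   T1   64 x 64 px, 2056 masked
#>   T2   64 x 64 px, 2056 masked

rep <- run_embedding_workflow(sim$ts, "T0", "T2", seed = 7)
rep
#> <hsi_workflow_report> embedding_driven workflow, sample 'synthetic-7'
#>   detected 411 T2 pixels (fraction 0.200)
#> <shift_report> T0 vs T2: band shift +0.002521, 1 crossing(s) at 580.2 nm

pixel_jaccard(rep$detected_tB_pixels, sim$truth$shifted_pixels$T2)
#> [1] 1
```

Reading the report: the UMAP(cosine) embedding of all four time points
contained a region populated almost exclusively by T2 pixels; the workflow
selected it (411 pixels — exactly the 20% shifted subpopulation, Jaccard 1
against the generator's ground truth), transferred the coordinates to T0,
and compared the region's mean l1-normalized spectra. They cross once, at
580.2 nm (the analytic crossing of the tilt model lies at 579.3 nm), and
the band-shift index is positive: blue channels lost weight, red channels
gained — a red shift.

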