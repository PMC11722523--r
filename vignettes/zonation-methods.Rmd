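---
title: "Methods: single-cell organelle phenotyping across the liver lobule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell organelle phenotyping across the liver lobule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

`lobulemap` quantifies how hepatocyte organelles are organized along the
periportal → pericentral (PP–PC) axis of the hepatic lobule. The pipeline
takes three registered 2-D fluorescence channels — mitochondria, lipid
droplets (LDs), actin — plus a manual vein annotation (one central-vein
mask, one or more portal-vessel masks), and produces one row per hepatocyte
containing organelle morphometry, mitochondria–LD contact metrics, and a
lobule coordinate.

The key modeling choices, in the order the data flow:

**Hepatocyte segmentation input.** Cells are bounded by a bright actin
ridge. For learned segmenters, the conventional input is a *combination
channel*: the percentile-normalized actin image plus a Gaussian-blurred
(σ = 2 px default) normalized mitochondria image, rescaled to [0, 1] — the
blur fills cell interiors with diffuse signal so cells read as filled
objects. The package's classical baseline (`backend_membrane()`) instead
uses the ridge structure directly: a three-class intensity split
(background / interior / ridge, thresholds at the midpoints of 1-D k-means
centers initialized at the 20/50/95th percentiles) isolates interiors as
connected components, with holes filled. The backend contract —
`(grayscale, params) → instance mask` — lets a trained model be dropped in
without code changes; the package never trains models. Organelles use
`backend_watershed()`: Gaussian smoothing, Otsu threshold, and a watershed
on the Euclidean distance transform so touching objects split at
constrictions.

**LD intensity filter.** Segmented LD candidates are filtered on their mean
intensity in the LD channel; with `"otsu"` the cut comes from a 1-D Otsu on
the distribution of per-object means. Whether such a filter should apply a
global or per-object threshold is genuinely open; we chose per-object mean
intensity with a configurable threshold because it is robust to object size
and makes the removal report interpretable (each removed label carries its
mean). The operation is idempotent at a fixed numeric threshold.

**Organelle → cell assignment.** An organelle belongs to the cell holding
the plurality of its pixels, provided that plurality reaches
`min_fraction` (default 0.5) of the organelle's area; otherwise it is
orphaned. Ties break toward the lower cell id so results are deterministic.

**Lobule coordinate.** For a cell centroid, `d_CV` and `d_PV` are exact
Euclidean distances to the nearest central-vein and portal-vessel pixels,
and the normalized central-vein distance is `r = d_CV/(d_CV + d_PV)`,
clamped to [0, 1]. The normalization distance is therefore *per cell*
rather than one global axis length: for a cell on the straight CV–PV
segment the two coincide, and for curved or oblique axes the per-cell form
degrades gracefully. A boundary-distance mode (minimum over the cell's own
pixels instead of the centroid) is available via a flag. Bins follow
`bin = clamp(N − floor(N·r), 1, N)` with `N = 12` by default: R1 is most
periportal, R12 most pericentral, boundaries are half-open and tie
handling is exact integer arithmetic, so the map from `r` to bin is
deterministic and monotone.

**Morphometry.** Area is pixel count × pixel-size²; eccentricity comes from
the eigenvalues of the second central moment matrix,
`e = √(1 − λ_min/λ_max)`; circularity is `4πA/P²`, clipped at 1.1 to absorb
rasterization overshoot on very small objects. The perimeter `P` is a
Cauchy–Crofton estimate using **eight** line directions (axes, diagonals,
knight moves), gap-weighted over orientation, with a half-line end
correction per oblique family for the boundary-grazing digital lines the
grid misses. Four directions — the more common choice — under-measure an
axis-aligned square by about 6%, which biases circularity upward by ~13%;
eight directions keep the worst-case anisotropy bias under ~2%, so a
rasterized disk reads ~0.97 and a square ~0.82 against the analytic π/4 ≈
0.785. A calibrated boundary-step estimator is available via
`perimeter = "boundary"` for cross-checks. We expose *circularity*, the 2-D
statistic, rather than inventing a 2-D "sphericity"; on sections the two
play the same role (1 = perfect disk/sphere, lower = elongated).

**Contact metrics.** Within each cell (cross-cell contacts are ignored),
`overlap_px = |M ∩ L|` counts mitochondria–LD overlapping pixels and
`overlap_pct = 100·|M ∩ L|/|L|` normalizes by LD pixels — i.e. the fraction
of droplet area engaged. The raw pixel count is the primary exported
quantity; the percent normalization (per LD, rather than per mitochondrion
or per cell area) is our reading of an otherwise under-specified statistic,
and both are exported so either convention can be recomputed. The shortest
mito-to-LD distance per droplet is the minimum over the droplet's pixels of
the exact Euclidean distance transform of the mitochondria mask (0 exactly
when the masks overlap), and the per-cell summary is the mean over
droplets. *Density* means organelle area fraction of the cell;
`count_density` (objects per 100 µm²) is exported alongside so either
reading of "density" is available. Missing values are encoded as `NA`
(empty CSV fields), never as zero: a cell with no droplets has
`ld_count = 0` but `ld_mean_area_um2 = NA`.

# Zonal statistics

`aggregate_by_bin()` computes per-bin, per-feature mean, SD (n − 1) and
cell count, keeping empty bins as explicitly missing. Because feature units
span orders of magnitude (µm², counts, fractions), profiles are z-scored
per feature across bins before PCA, clustering and correlation; the
centering/scaling constants are retained so the transform round-trips
exactly. PCA is the projection of the centered bins × features matrix onto
its top right-singular directions; component signs are fixed by making each
loading's largest-magnitude entry positive, so scores are reproducible to
the 1e-8 level against an independent eigendecomposition. Hierarchical
clustering defaults to average linkage on Euclidean distances of z-scores —
configurable, since no single convention is canonical — and cutting the row
dendrogram at `k` yields flat zone labels. Cross-condition similarity is
the Pearson correlation between bin feature vectors computed on the shared
feature set after pooling both conditions into one z-score frame, so both
conditions sit on one scale; a profile against itself gives a symmetric
matrix with unit diagonal by construction.

**Pooling.** A single 2-D lobule image bins only a handful of cells per
zonal bin (about six at the defaults), so per-bin means from one image are
Poisson-noisy and adjacent bins can swap rank. Zonal profiling protocols
therefore pool many PP–PC axes per condition before averaging; the
package's validation follows the same design and pools the cells of five
simulated lobules before computing per-bin gradients. Single-image
profiles remain available — their SD columns make the per-bin uncertainty
explicit.

# The synthetic lobule generator

The generator is the test bed for every downstream stage: it renders
channels *from* ground-truth masks, so recovery can be scored exactly.

Geometry defaults, chosen once as the study conditions: central vein and
portal vessel centers 250 µm apart; 14 hepatocytes per axis (the midpoint
of the 12–16 cells typically spanning an axis) in 5 rows; hepatocyte
radius 7.5 µm; vein radii 15 µm (CV) and 10 µm (PV); pixel size 0.2 µm/px
— a stand-in for unspecified acquisition settings, configurable
throughout. Cells are Voronoi regions of jittered row-grid seeds, capped
at 1.3 × the cell radius and excluding vein pixels — simple convex shapes
suffice because all downstream operators are shape-agnostic. Portal
vessels sit at high *x* and the central vein at low *x* by default; the
orientation is generator metadata and nothing downstream assumes it.

Zonal structure enters through gradients over the true `r` of each cell:
`ld_count(r)`, `ld_radius_um(r)`, `mito_count(r)`, `mito_elongation(r)`,
`mito_area_fraction(r)` and `contact_fraction(r)`, each either a linear
`c(pc, pp)` pair or an arbitrary function (step functions plant discrete
zones for clustering tests). Counts are Poisson draws from the gradient at
the cell's `r`; mitochondria are rasterized ellipses whose size follows the
area-fraction gradient given the drawn count and elongation; LDs are disks
with log-normal radius jitter. A droplet flagged as contacting is placed so
its mask shares at least one pixel with a mitochondrion of the same cell
(target overlap depth ~1.5 px); placement falls back to centering on
mitochondrion pixels and *skips* the droplet rather than ever placing a
"contacting" droplet without overlap, so ground-truth contact flags are
consistent with the masks by construction (they are re-derived from the
final masks regardless). Channels render organelle pixels at fixed bright
levels over a constant background, with Gaussian readout noise (σ = 0.02
default) and optional Poisson shot noise, then quantize to the 16-bit grid
so TIFF round trips are bit-identical. With σ = 0, re-thresholding a
channel above background recovers the ground-truth pixel set exactly.

The dietary presets encode qualitative phenotypes: **control** concentrates
droplets pericentrally (LD count decreasing with `r`) with contacts only in
the pericentral third (`contact_fraction` reaching 0 for r > 1/3);
**fasted** elevates LD counts lobule-wide with high contact fraction
everywhere except the most pericentral sixth of the axis, and elongated
mitochondria throughout; **western_diet** has large periportal droplets,
uniformly low contact fraction, and rounder mitochondria.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optical blur and PSFs, uneven illumination,
3-D structure collapsed into sections, irregular cell shapes, binucleate
hepatocytes, autofluorescence, vessel lumens' texture, and segmentation
errors of learned models. Passing recovery tests demonstrates that the
*operators* are correct (distances exact, geometry matching brute-force
moments, aggregation faithful), not that any particular segmentation model
will be accurate on tissue.

# Validation design and problem sizes

The test-bed sizes are chosen so the full suite exercises every stage at
realistic geometry: validation runs use five seeds per condition, each a
full 250 µm lobule of ~70 cells (~1700 mitochondria, ~400 droplets),
pooled as described above for gradient recovery; zone-recovery runs plant
three regimes aligned on bin boundaries (R1–R3 / R4–R10 / R11–R12) and
score flat clusters at k = 3 by adjusted Rand index. Oracle tests compare
overlap counts, minimum distances, distance maps, moments and areas
against brute-force enumeration on instances up to 64 × 64, where
exhaustive computation is exact. Pipeline determinism is checked by
byte-comparing the CSV outputs of two runs at the same config and seed;
all randomness flows from the single top-level seed (condition *i*
simulates at `seed + i − 1`).

# Known limitations

- 2-D only: no z-stacks, no 3-D sphericity, no surface rendering.
- The classical cell backend needs a ridge-bounded appearance; densely
  packed tissue without a membrane signal will under-segment. The backend
  contract exists precisely so a trained model can replace it.
- Contact metrics are pixel-overlap proxies, not membrane-apposition
  distance bands; at 0.2 µm/px an "overlapping pixel" conflates touching
  and true overlap.
- Per-bin SDs from one image reflect few cells; pool axes for stable
  profiles.
- Occasional boundary-bin ambiguity in zone recovery: when a regime
  boundary bin holds very few cells, its average can tip toward the
  neighboring regime and flat clusters then mislabel that single bin.
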