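# lobulemap

Single-cell organelle phenotyping across the liver lobule.

Hepatocytes divide labor along the periportal → pericentral (PP–PC) axis of
the hepatic lobule: lipid droplet (LD) content, mitochondrial shape and
mitochondria–LD contact sites all change with a cell's position between a
portal vessel (PV) and the central vein (CV), and they remodel under
nutritional challenges such as fasting or a Western diet. `lobulemap` turns
multi-channel fluorescence images of lobules (mitochondria, LDs, actin) into
per-hepatocyte organelle morphometry mapped onto lobule coordinates, and
aggregates those single-cell features into zonal statistics. It is aimed at
cell biologists quantifying organelle zonation from 2-D tissue sections, and
it ships a ground-truthed synthetic lobule generator so the whole pipeline
can be exercised and validated without microscopy data.

## What it computes

For each segmented hepatocyte with centroid distances `d_CV` and `d_PV` to
the nearest central-vein and portal-vessel pixels, the normalized
central-vein distance is

    r = d_CV / (d_CV + d_PV),  r in [0, 1]

and the zonal bin is `bin = clamp(N − floor(N·r), 1, N)` with `N = 12`, so
R1 is the most periportal bin and R12 the most pericentral. Per organelle
(mitochondrion or LD) the package reports area, perimeter (8-direction
Crofton estimate), circularity `4πA/P²`, moment eccentricity
`√(1 − λ_min/λ_max)` and mean intensity; per cell it aggregates counts,
densities (organelle area fraction and objects per 100 µm²) and the
mitochondria–LD contact metrics: overlapping pixels `|M ∩ L|`, percent
overlap `100·|M ∩ L|/|L|` and the shortest mito-to-LD distance per droplet.
Bin-level profiles (mean ± SD per feature), PCA embeddings, hierarchical
cluster maps and cross-condition Pearson correlation matrices reproduce the
standard zonation read-outs.

Segmentation uses a pluggable backend contract (grayscale image → instance
mask), with two classical baselines included: threshold + watershed on the
distance transform for bright organelles, and a membrane/band backend for
ridge-bounded hepatocytes. A learned model can be plugged in without code
changes. LD segments pass through a per-object intensity filter (1-D Otsu
over object means) to suppress false positives.

## Worked example

```r
library(lobulemap)
library(dplyr)

sim <- simulate_lobule(condition_preset("control"), seed = 1)
cells <- build_feature_table(
  sim$truth$cell_mask, sim$truth$mito_mask, sim$truth$ld_mask,
  channels = sim$channels, veins = sim$truth$veins,
  config = list(pixel_size_um = 0.2))

cells |>
  select(cell, bin, r, ld_count, ld_density, mito_count,
         mito_mean_circularity, overlap_px) |>
  head(4)
#>    cell   bin      r ld_count ld_density mito_count mito_mean_circularity
#> 1     1    11 0.0941        6     0.0386         31                 0.761
#> 2     2    11 0.144         8     0.0588         26                 0.762
#> 3     3    10 0.206         4     0.0260         29                 0.791
#> 4     4     9 0.270         6     0.0399         26                 0.789

axis_summary(sim$truth$cells, sim$truth$veins, 0.2)
#>   axis_length_um n_cells
#> 1            250      14
```

One synthetic control lobule yields 70 hepatocytes on a 250 µm CV–PV axis
with 14 cells per axis row. Pericentral cells (bins R11–R12, `r` near 0)
carry more droplets than periportal ones; aggregating per bin makes the
planted gradient visible:

```r
prof <- aggregate_by_bin(cells, condition = "control")
tidy(prof) |> filter(feature == "ld_count", bin %in% c(1, 6, 12))
#>     bin bin_label feature   mean    sd     n
#> 1     1 R1        ld_count  1.67  1.53     3
#> 2     6 R6        ld_count  5.4   2.07     5
#> 3    12 R12       ld_count 11.7   2.08     3

pca <- prof |> standardize_profile() |> pca_embed(n_components = 2)
glance(pca)
#>   n_components total_var_explained
#> 1            2               0.777
```

LD count rises from 1.7 per cell in R1 to 11.7 in R12, and two principal
components explain 78% of the between-bin feature variance, with the bins
ordered along PC1 — neighboring bins embed near each other.
`autoplot()` methods exist for profiles, PCA embeddings, cluster maps,
correlation matrices and overlap heatmaps.

The same stages run from the shell via `inst/scripts/lobulemap`
(`simulate`, `segment`, `profile`, `zonate`, `all`) with a YAML config, a
JSON run manifest, and plain TIFF/CSV intermediates.

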