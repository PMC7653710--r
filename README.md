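# plaqband

Quantitative neuropathology of β-amyloid plaques and their proximity
bands, for researchers measuring plaque-associated pathology in
multi-channel fluorescence sections: how many dystrophic neurites surround
each plaque, how strongly microglia cluster against it, how much lysosomal
marker the clustered cells carry, and whether a metabolic condition (a
Western-style diet inducing type-2 diabetes) changes any of that.

## What it computes

**Segmentation.** Each channel is max-projected, background-subtracted
(rolling ball: grayscale opening with a flat disk), Gaussian-smoothed and
thresholded with the classical automatic operators — Otsu for the plaque
dye (X-34-style), Intermodes for the neurite marker, Moments for
microglial/lysosomal markers, Li for the morphometry path. All four are
implemented from their original definitions and verified against
exhaustive-search and fixed-point oracles.

**Plaque and band quantification.** Plaques are 8-connected components
with equivalent diameter d = 2·√(A/π); components with d ≤ 9.9 µm are not
counted. Around each plaque outline the proximity band (annulus) holds the
pixels within 30 µm by exact Euclidean distance, interior excluded. Per
plaque and marker the package reports positive area inside the plaque and
in the band, mean band intensity, band object counts (dystrophic
neurites), plaque burden (plaque area as % of the ROI), and
plaque-associated microglia counted separately within and around the
plaque from watershed-separated somata.

**Skeleton morphometry.** Zhang–Suen thinning to 1-px skeletons; process
endpoints, junction counts and process length read from the reduced curve
graph (corner-shortcut diagonals excluded), with spur pruning and
single-cell selection.

**Statistics.** Two-way factorial ANOVA (Type II), Mann–Whitney U (exact
by enumeration for small samples), Kruskal–Wallis, Pearson/Spearman
correlations, Fisher's exact test, half-up printed proportions, a
response-concordance classifier for paired Z statistics (|Z| > 2.5 rule),
2^−ΔΔCt fold changes, and the human biopsy-cohort computations (BMI,
HOMA-IR variants, metabolic grouping, group summary rows).

**Synthetic sections.** A seeded generator plants plaques (log-normal
diameters), diameter-dependent neurite counts, condition-scaled
plaque-associated microglia with full process topology, and lysosomal
puncta, renders 4-channel sections with noise and background gradients,
and returns complete ground truth — every downstream stage is tested
against it.

## Worked example

Simulate a control section, quantify it, and compare with the planted
truth:

```r
library(plaqband)

cfg <- section_config(field_size_um = c(400, 400), plaque_density = 40,
                      microglia_per_plaque_mean = 8, seed = 1)
s <- generate_section(cfg)
q <- quantify_section(s$stack)

nrow(q$plaques)                      # detected plaques
#> [1] 5
head(q$band_quant[q$band_quant$marker == "neurite",
                  c("plaque_id", "area_in_band_um2", "n_objects_band")], 3)
#>   plaque_id area_in_band_um2 n_objects_band
#> 3         1              134              5
#> 6         2              255              9
#> 9         3              522             16
head(q$microglia_counts, 3)          # per-plaque within/around counts
#>   plaque_id n_within n_around n_total
#> 1         1        0       13      13
#> 2         2        1        5       6
#> 3         3        1        4       5
```

The bundled analysis (`analysis/01_simulate_sections.R` …
`05_cohort_table.R`) runs the full study: 18 sections (3 animals × 3
sections × 2 conditions, condition factor 0.6), quantification,
morphometry and statistics. On the shipped seeds it prints, among others:

```
Mean microglia/plaque: 7.68 (control) vs 5.26 (condition)
Endpoint counts exact for 30/30 cells
Median |length error|: 2.4%
Per-subject BMI reproduced exactly: 12/12
Evidence of lipid vacuoles: 20/24 = 83% (TWD), 5/22 = 23% (STD)
Fisher's exact on evidence table: OR = 17.0, p = 7.4e-05
```

— the suppressed microglial clustering in the condition arm, exact
recovery of planted process topology, the reproduced biopsy-cohort table,
and the diet effect on fatty-liver scoring. (The printed proportion for
20/24 follows the exact arithmetic, 83%.)

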