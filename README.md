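# paleoiso

Bone-collagen isotope offsets and a quantile-conditional drought index
for Neolithic site catchments.

## What this is for

Human bone-collagen carbon and nitrogen stable isotope ratios
(δ13C ‰ VPDB, δ15N ‰ AIR) record diet, but the signal mixes two
drivers: cultural food choices and the local environmental baseline.
`paleoiso` implements a pipeline — motivated by large diachronic
collagen datasets from agropastoral prehistory such as the Neolithic
Carpathian Basin — that lets an analyst test the two against each other:

1. **Collagen QC** — preservation screening on atomic C/N (2.9–3.6),
   collagen yield (≥ 1 %), %C (≥ 13) and %N (≥ 4.8), with explicit
   exclusions and a chronological criterion; every rejected row carries
   reason codes.
2. **Offsets and tests** — site-level trophic offsets
   Δ = mean(human) − mean(herbivores + omnivores) per isotope (a
   δ15N offset of 3–6 ‰ is the expected trophic step; values below
   ~3 ‰ point to a plant-dominated protein intake), plus one-way ANOVA
   and Kruskal–Wallis group tests and χ²/Fisher contingency tests.
3. **Drought index** — DEM sink filling (priority-flood),
   precipitation-weighted D8/Rho8 flow accumulation, then a monthly
   conditional model: quartile classes of P and T combined through a
   4×4 ordinal rule (CON), refined by flow-accumulation quartiles
   (wCON) so major flow paths class wetter. Low class = drought
   vulnerable, high class = humid.
4. **Catchment clustering** — environmental feature vectors from a
   3000 m radius window around each site (12 monthly wCON grids +
   one-hot soil composition), PCA to 99 % variance, K-means
   (k-means++, 25 restarts) with gap-statistic and silhouette
   selection of k, and a cluster × region independence test.

A seeded synthetic generator (terrain, seasonal climate, soil mosaics,
sites, isotope tables with known trophic offsets) emulates every input,
so the whole pipeline runs and is tested without any external download.

## Worked example

```r
library(paleoiso)
cfg <- synthetic_config(seed = 3, grid_shape = c(48L, 48L), n_sites = 20)
res <- run_pipeline(pipeline_config(seed = 3, synthetic = cfg,
                                    k_max = 6, gap_B = 10),
                    out_dir = "run1")
res$summaries
#>  group isotope   n     min      q1  median      q3     max
#>  fauna    d13C 183 -22.145 -20.684 -20.338 -19.993 -19.329
#>  fauna    d15N 183   6.130   7.119   7.541   7.959   8.767
#>  human    d13C 191 -21.272 -20.422 -19.961 -19.649 -18.670
#>  human    d15N 191   9.187  10.233  10.676  11.195  13.622
head(res$offsets, 4)
#>  site_id period  culture n_human n_fauna offset_d13C offset_d15N
#>     S001     MN     ALBK      10      10       0.330        3.09
#>     S002     EN Starcevo      10       9       0.515        2.86
#>     S003     EN Starcevo      10       9       0.275        2.99
#>     S004     LN  Lengyel       9       9       0.396        2.88
res$region_test$p_value
#> [1] 0.1086266
```

Reading the numbers: fauna δ13C clusters around −20.3 ‰ (a C3
terrestrial baseline) and humans sit ~0.35 ‰ above it; the δ15N offsets
near 3.1 ‰ are one trophic step, i.e. animal protein in the diet but no
more. The cluster × region test here (p ≈ 0.11) shows this particular
synthetic landscape induces no significant regional structure in the
environmental typology — under a strong west–east climate gradient the
same test drops below 0.01 (see the acceptance script).

Each run directory holds the QC'd tables, offsets, summary statistics,
ASCII-grid rasters (DEM, flow accumulation, 12 monthly wCON), site
GeoJSON, cluster assignments with silhouettes, and a provenance
manifest; reruns with the same configuration are byte-identical for
deterministic stages.

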