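Package: paleoiso
Title: Bone-Collagen Isotope Offsets and a Quantile-Conditional Drought
    Index for Neolithic Site Catchments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse carbon and nitrogen stable isotope ratios in
    human and animal bone collagen alongside a gridded environmental model
    of drought vulnerability. Provides collagen preservation quality
    filtering (atomic C/N, collagen yield, elemental percentages),
    site-level human-fauna trophic-offset statistics with one-way ANOVA and
    Kruskal-Wallis group tests, DEM sink filling and precipitation-weighted
    D8/Rho8 flow accumulation, a monthly quantile-conditional climate index
    (CON) refined by flow accumulation quartiles (wCON), and environmental
    K-means clustering of fixed-radius site catchments with gap-statistic
    and silhouette selection of k. A seeded synthetic-data generator
    (terrain, seasonal climate, soil mosaics, sites, isotope tables with
    known trophic offsets) makes every stage testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
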