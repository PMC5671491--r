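Package: gdgtproxy
Title: GDGT Lipid Proxy Indices, Calibration Screening, and Archaeal Source Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes isoprenoid glycerol dialkyl glycerol tetraether (GDGT)
    proxy indices (TEX86, ring indices, Methane Index, BIT and related
    ratios) from fractional-abundance tables, screens samples against the
    global ring-index/TEX86 core-top calibration, and quantifies the
    association between cyclopentyl-GDGT enrichment and Marine Group II
    Euryarchaeota 16S rRNA gene abundance by group summaries and ordinary
    least-squares regression. Includes a two-endmember
    (Thaumarchaeota/MG-II) compositional mixing simulator with Dirichlet
    and lognormal qPCR noise for end-to-end testing and parameter-recovery
    studies, and a packaged estuarine transect dataset of per-sample index
    values and gene abundances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
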