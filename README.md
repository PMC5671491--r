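# gdgtproxy

Proxy-index computation, calibration screening, and archaeal
source-attribution statistics for isoprenoid GDGT lipid data.

TEX86 — the tetraether index of 86 carbons,

    TEX86 = ([GDGT-2] + [GDGT-3] + [Cren']) / ([GDGT-1] + [GDGT-2] + [GDGT-3] + [Cren'])

— is a widely used sea-surface-temperature proxy that assumes the GDGT pool
is produced by Marine Group I Thaumarchaeota. In estuaries and coastal
seas, Marine Group II Euryarchaeota can contribute cyclopentane-bearing
GDGTs, inflating the ring index and biasing TEX86-derived temperatures.
This package is for organic geochemists and geomicrobiologists who need to
screen such samples and quantify the non-thermal source:

- **Indices** from percent fractional abundances: `tex86()`,
  `ring_index_1()` (the core-top calibration form,
  `RI = (g1 + 2 g2 + 3 g3 + 4 cren + 4 cren')/100`), `ring_index_2()` (a
  crenarchaeol-free variant substituting GDGT-4), `methane_index()`,
  `bit_index()`, `pct_gdgt2()`, `gdgt_ratios()`.
- **Screening**: `tex86_temperature()` (`T = 68.4 log10(TEX86) + 38.6`),
  `predicted_ri()` (`RI = 3.32 TEX86² − 0.77 TEX86 + 1.59`), `delta_ri()`
  with the ±0.3 calibration zone, and the standard advisory QC flags
  (BIT > 0.2, GDGT-2/cren > 0.4, MI > 0.5, GDGT-0/cren > 2, %GDGT-2 > 45).
- **Statistics**: `group_summary()`, `welch_t_test()`, `ols_regression()`,
  and `regression_screen()` — OLS of index values on the qPCR
  `[MG-II 16S]/[Archaea 16S]` gene-copy ratio, laid out variables × lipid
  pools.
- **Simulation**: `simulate_transect()`, a two-endmember
  (Thaumarchaeota + MG-II) compositional mixing model with Dirichlet and
  lognormal qPCR noise, for end-to-end testing and parameter recovery.
- A packaged 26-sample estuarine transect (`load_table1_fixture()`):
  river → estuary → coastal-sea SPM and surface sediments with per-pool
  TEX86/RI_2 and gene abundances for 12 SPM samples.

See the vignette (`vignettes/gdgt-proxy-screening.Rmd`) for the model
assumptions, parameter defaults, and known limitations.

## Worked example

```r
library(gdgtproxy)

ds <- load_table1_fixture()
ds
#> <gdgt_dataset> 26 samples (river: 8, mixing: 6, sea: 4, sediment: 8)
#>   profiles: absent | indices: 78 rows
#>   provenance: packaged Pearl River estuary transect table

# Ring-index (RI_2) regressed on the MG-II/archaea gene ratio,
# per lipid pool, over the 12 SPM samples with qPCR data:
regression_screen(ds, "ri2")
#> # A tibble: 3 × 7
#>   variable pool        r_squared  p_value slope intercept     n
#>   <chr>    <chr>           <dbl>    <dbl> <dbl>     <dbl> <int>
#> 1 ri2      CL              0.485 0.0119   0.592     0.205    12
#> 2 ri2      total_IPL       0.509 0.00921  0.800     0.244    12
#> 3 ri2      phospho_IPL     0.718 0.000499 1.13      0.147    12

group_summary(ds, "gene_ratio")
#> # A tibble: 3 × 6
#>   water_type variable       n      mean        sd    sd_pop
#>   <fct>      <chr>      <int>     <dbl>     <dbl>     <dbl>
#> 1 river      gene_ratio     2 0.0000731 0.0000987 0.0000698
#> 2 mixing     gene_ratio     6 0.257     0.0934    0.0853
#> 3 sea        gene_ratio     4 0.103     0.0655    0.0567
```

The regression says: the phosphatidyl intact-polar-lipid pool — the pool
closest to living biomass — carries the strongest association between
cyclopentane-ring enrichment and MG-II gene abundance (R² = 0.72,
p < 0.001, n = 12), and the MG-II share of archaea peaks in the estuarine
mixing water (mean gene ratio 0.26 vs 0.10 in seawater and ~10⁻⁴ in river
water). That is the signature of an estuarine MG-II source of ringed
GDGTs.

A full report bundle (per-sample indices + screening flags, group
summaries, regression tables, run log):

```r
run_pipeline(list(input = list(type = "fixture"),
                  ri_for_zone = "ri2", out_dir = "report"))
```

or from a shell, including synthetic-data generation:

```sh
Rscript inst/scripts/gdgt-pipeline.R fixture  --out table1.csv
Rscript inst/scripts/gdgt-pipeline.R simulate --seed 7 --n 50 --out transect.csv
Rscript inst/scripts/gdgt-pipeline.R run      --config config.yaml --out report/
```

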