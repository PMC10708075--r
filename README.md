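# flavoromics

Volatile flavoromics for two-group GC-MS experiments: from replicate peak
tables to relative contents, ROAV-based key-flavor identification, a
bipartite flavor network, and signature-compound screening that fuses
OPLS-DA VIP with random-forest Gini importance.

## Who this is for

Analysts of headspace GC-MS VOC profiles (fruit, fermented foods,
beverages) comparing two sample groups — e.g. two species or two
processing conditions — who want a scripted, tested version of the
standard flavoromics workflow instead of spreadsheet + point-and-click
chemometrics.

## The statistics at the core

For sample *s* and compound *c*, relative content is the area-normalized
percentage `C = 100 · a_sc / Σ_c' a_sc'`.  With odor threshold *T*
(mg/kg, water):

```
OAV  = C / T                    odor activity value
ROAV = 100 · OAV_i / OAV_max    per group; ROAV ≥ 1 → key flavor compound
```

Key compounds and their odor descriptors form a bipartite network whose
descriptor nodes weigh the summed ROAVs of their compounds.  For the
group contrast, an OPLS-DA model (from-scratch NIPALS; unit-variance
scaling; one orthogonal component; 7-fold venetian-blind Q²;
permutation validation) yields per-compound VIPs, and a seeded random
forest yields Gini importances.  The two are min–max normalized and
averaged:

```
X_A = (X_Vnom + X_Gnom) / 2     signature ⇔ VIP ≥ 1 and X_A > 0.5
```

The package ships a published two-species rose-fruit study (groups RR
and RS, 61 VOCs, 12 with odor thresholds) as plain-text fixtures, plus a
seeded synthetic generator with planted discriminant compounds.

## Worked example

```r
library(flavoromics)

profiles   <- rosa_group_profiles()     # packaged study: RS and RR
thresholds <- rosa_odor_thresholds()

roav_rr <- compute_roav(profiles$RR, thresholds)
roav_rr
#> roav_result 'RR': 6 key, 3 modifier, 49 without threshold

head(subset(as.data.frame(roav_rr), has_threshold,
            select = c(compound, content, threshold, roav)), 6)
#>                    compound content threshold    roav
#> 1           ethyl butanoate    3.97    0.0009 100.000
#> 2           ethyl hexanoate    5.46    0.0050  24.756
#> 3                   nonanal    1.00    0.0011  20.609
#> 4           ethyl caprylate    3.44    0.0193   4.041
#> 5 (3z)-3-hexen-1-yl acetate    2.85    0.0310   2.084
#> 6                   styrene    3.75    0.0650   1.308
```

Ethyl butanoate is RR's most odor-active compound (ROAV 100); the six
compounds with ROAV ≥ 1 are RR's key flavor compounds.  Their descriptor
network shows what RR smells like:

```r
build_flavor_network(roav_rr, thresholds)
#> flavor_network 'RR': 6 key compounds, 18 descriptors, 30 edges
#> top descriptors by summed ROAV:
#>  descriptor summed_roav degree
#>      fruity   130.88051      4
#>   pineapple   124.75567      2
#>      brandy   104.04067      2
#>        waxy    49.40545      3
#>       sweet    32.18840      4
```

Fusing the study's printed VIP and Gini columns and applying the screen:

```r
vg     <- rosa_vip_gini()
fusion <- fuse_importance(vg[c("compound", "vip")], vg[c("compound", "gini")])
screen_signature(fusion)$compound
#> [1] "(e)-2-hexenal"   "ethyl caprylate" "ethyl butanoate" "beta-ocimene"
```

These four compounds pass VIP ≥ 1 and X_A > 0.5 — the signature
differential flavor compounds separating the two species.  (Methyl
salicylate, X_A = 0.52, is excluded by its VIP of 0.91.)

For replicate-level data — real or simulated — `run_pipeline()` drives
all stages and gates the signature screen on model validity (Q² > 0.5
and permutation p < 0.05):

```r
cfg <- synthetic_preset("strong-signal", seed = 7)
rep <- run_pipeline(generate_peak_table(cfg), generate_threshold_table(cfg),
                    outdir = "run", seed = 7)
```

A thin command-line wrapper with per-stage subcommands is installed at
`system.file("cli", "flavoromics", package = "flavoromics")`.

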