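# dnbtip

Dynamic-network-biomarker (DNB) analysis of tipping points in time-series
expression data, with a synthetic-data generator, a differential-expression
stand-in, pathway/network ranking of candidate driver genes, and a bistable
toggle-switch model of the top driver pair.

## The problem

Chronic disease processes often end in an abrupt, hard-to-reverse
transition rather than deteriorating linearly. DNB theory characterises
the low-resilience state just before such a transition by the behaviour of
a small *dominant group* of genes: at the tipping point their within-group
correlation and replicate variance rise sharply while their correlation to
the rest of the transcriptome falls. The early-warning statistic is the
composite index, evaluated per candidate group `M` per timepoint `t`:

```
CI(M, t) = PCC_in(M, t) * SD_in(M, t) / PCC_out(M, t)
```

where `PCC_in` is the mean absolute Pearson correlation over within-group
gene pairs across replicates, `PCC_out` the mean absolute correlation
between group and non-group genes, and `SD_in` the mean replicate standard
deviation of the group. The timepoint with the sharpest CI peak, validated
by a permutation test, is the called tipping point, and the group attaining
it is the DNB — the candidate set of transition-driving genes.

The package is written for time-course designs of the kind used in
experimental fibrosis studies: treated animals sampled at several
timepoints with a few replicates each, plus untreated controls at a subset
of timepoints, starting from a genes x samples count or log2 expression
matrix.

## Worked example

Simulate the reference design — 500 genes, a planted 20-gene module whose
correlation (0.9) and variance (3x) rise at week 9 of a 3/5/9/14/17-week
course, five replicates per timepoint, controls at weeks 3/9/17 — and run
the estimator:

```r
library(dnbtip)
sim <- simulate_expression(simulation_design(seed = 9))
fit <- select_dnb(sim$dataset, sim$sheet, seed = 1)
print(fit)
#> Dynamic network biomarker analysis
#>   5 treated timepoints; dominant-module CI per timepoint:
#>  time module_size pcc_in pcc_out  sd_in    ci
#>     3           7 0.8135  0.4182 0.7862 1.529
#>     5           7 0.8799  0.4009 0.7397 1.623
#>     9          24 0.9272  0.4056 1.1755 2.687
#>    14          32 0.8389  0.3614 0.5488 1.274
#>    17           6 0.7966  0.4203 0.8164 1.547
#>   tipping point: t=9 (permutation p=0.004975, 200 permutations), 24 DNB genes
length(intersect(fit$dnb_genes, sim$truth$module))
#> [1] 20
```

The CI profile is flat except at week 9, where the dominant module's
within-correlation (0.93) and member SD (1.18, versus ~0.5 background)
spike; the permutation test (200 replicates, each destroying cross-gene
co-fluctuation while preserving every per-gene per-timepoint SD) rejects at
p = 0.005, and the reported 24-gene module contains all 20 planted genes.
`plot(fit)` draws the CI profile with the call highlighted;
`sample_dispersion()` gives the replicate-scatter QC table.

Downstream, `differential()` applies the conventional fold-change/FDR
screen before versus after the tipping point, `intersect_dnb_deg()`
intersects DEGs with the DNB, and `rank_dnbs()` orders candidate drivers by
fibrosis-pathway membership counts and network-linked DEGs. The bistable
mechanism of the top driver pair is explored with the toggle model:

```r
m <- toggle_model()          # alpha = 3, cooperativity = 2
print(m)
#> toggle_model: alpha = (3, 3), beta = (2, 2)
#>   3 fixed point(s): (0.382, 2.618) stable_node, (1.213, 1.213) saddle,
#>                     (2.618, 0.382) stable_node
#>   bistable: TRUE
```

Two stable states (one x-low/y-high "normal", one x-high/y-low "disease")
are separated by a saddle; `bifurcation_scan(beta = 2)` locates the
critical synthesis rate at which bistability appears, and
`stochastic_simulate()` shows fluctuation variance growing as that
threshold is approached — the dynamical counterpart of the rising DNB
signal. `run_pipeline(pipeline_config(...))` chains all stages under one
config and seed and writes a consolidated JSON report.

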