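# dvcscan

Differential variability and correlation (DVC) analysis for single-cell
transcriptomes.

## What it does, and for whom

During a cell-state transition — e.g. neural stem cells (NSCs)
differentiating through transit-amplifying progenitors (TAPs) into
astrocytes — key regulators such as *Ascl1*, *Hes1* and *Dll1* oscillate
in the progenitor state. Because single cells are unsynchronized
snapshots, oscillation shows up not as a mean change but as **high
cross-cell variability** together with **tight co-expression** that both
collapse after the transition. Genes with this signature are invisible to
mean-level differential expression yet are strong candidates for
triggering or marking the upcoming transition.

`dvcscan` is for transcriptomics researchers who have a genes × cells
count matrix with per-cell state labels and want to rank genes by this
signature. Per gene, between an early state *E* and a late state *L* (on
log2-CPM expression, TMM-normalized):

- **ΔV = log2(sd_E / sd_L)** — change of expression variability, tested
  with a Levene test and Benjamini–Hochberg correction;
- **ΔC = r̄_E − r̄_L** — change of the mean Pearson correlation with
  co-module members, the modules being detected in the earliest state by
  Ward clustering on 1 − r with a dynamic (hybrid) tree cut
  (minimum module size 100);
- **STS** (state transition score) — by default the mean of the
  rank-normalized ΔV and ΔC, each mapped so the strongest
  decrease-from-early scores 1. High-STS genes are the **DVC genes**.

Around this core: one-sided hypergeometric enrichment (`phyper`-style,
against the analyzed-gene universe), per-module enrichment of
differential-variability calls, TF-target sets built by intersecting
ChIP-seq peaks with open chromatin and collecting genes within 1 Mb,
a correlation-≥ 0.7 network export (GraphML/SIF, Cytoscape-loadable),
a Welch-test DEG baseline for contrast, and a negative binomial simulator
with planted oscillatory modules that makes every stage testable without
any download.

## A worked example

```r
library(dvcscan)

cfg <- simulation_config(seed = 42)   # 10,000 genes; 92 NSC / 27 TAP / 22 astrocyte cells;
sim <- simulate_counts(cfg)           # 3 planted oscillatory modules of 150 genes
rc  <- run_config(counts = sim$counts, outdir = "dvc_run", seed = 42, dvc.top_n = 675)
res <- run_pipeline(rc)
res$modules
#> dvc_modules: 9815 genes, 3 modules (state 'NSC', min size 100)
#>   black: 150
#>   magenta: 150
#>   red: 150
#>   unassigned: 9365
print(res$sts$NSC_vs_astrocyte, 3)
#> dvc_sts: 450 scored genes (NSC -> astrocyte, combiner rank_sum), 450 flagged
#>     gene  delta_v   delta_c       sts rank dvc_flag
#> 1 g00257 1.861118 0.8615371 0.9922222    1     TRUE
#> 2 g00381 1.833456 0.8495028 0.9788889    2     TRUE
#> 3 g00154 1.641448 0.8537630 0.9477778    3     TRUE
```

Each scored gene's variability roughly halves after the transition
(`delta_v ≈ 1.6` means the early SD is ~3× the late SD) and its mean
within-module correlation drops by ~0.85 — the planted
oscillation-then-harmonize signature, recovered at the top of the
ranking. `run_pipeline` writes the filtered counts, normalization report,
log2-CPM matrix, module table, dendrogram (Newick), one STS table and
DVC gene list per state pair, per-module enrichment tables, the
thresholded network (GraphML) and a provenance JSON into `outdir`.

A thin CLI over the same functions ships in `inst/scripts/dvcscan`
(`dvcscan run --config cfg.yaml`, `simulate`, `enrich`, `net`,
`run --show-defaults`).

## Package layout

- `R/` — preprocessing, co-expression, DVC/STS, enrichment, network,
  simulator, pipeline orchestration
- `tests/testthat/` — unit, property and end-to-end benchmark tests with
  independent brute-force oracles
- `vignettes/dvc-analysis.Rmd` — the methods account: model, parameters,
  what the simulator does and does not emulate, numerical choices,
  limitations
- `scripts/acceptance.R` — see above
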