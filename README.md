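# broilerDEA

Relative-efficiency benchmarking of integrated broiler production with
**Data Envelopment Analysis (DEA)**.

Integrated poultry producers are compensated through batch performance
indices, and the agro-industry's return on working capital hinges on unit
production cost. This package asks, batch by batch, the question those
indices cannot: *given what every other producer achieved, could this batch
have delivered its live weight with proportionally less housing, time,
feed, mortality and cost?* It answers with the two classical DEA models —
CCR (constant returns to scale) and BCC (variable returns, adding the
convexity constraint ∑λ = 1) — in input and output orientation, solved as
envelopment linear programs

θ\*(o) = min { θ : ∑ₖ λₖ xₖ ≤ θ x(o), ∑ₖ λₖ yₖ ≥ y(o), λ ≥ 0 },

by a two-phase simplex (phase 2 maximises slacks at the optimal radial
factor, the standard realisation of the non-Archimedean ε). On top of the
four model runs it provides:

- **inverted-frontier and composite ranking** — the same model on the
  role-swapped table scores proximity to *worst* practice; composed =
  (standard + 1 − inverted)/2 and its max-normalisation discriminate the
  efficient units;
- **zootechnical panel** — viability, daily weight gain (g/bird/day over
  surviving birds), feed conversion ratio and the European production
  efficiency factor PEF = viability × DWG / (10 × FCR), plus
  direction-aware gap reports against a benchmark batch;
- **a packaged 31-batch reference dataset** from a Brazilian integrated
  production system, and **simulators** for realistic farm tables and for
  planted frontiers with analytically known efficiencies.

## Worked example

```r
library(broilerDEA)

tab <- broiler_batches()          # 31 batches, 5 inputs, 1 output
res <- dea(tab, dea_model("crs", "input"))
print(res, digits = 2)
#> DEA model: CRS, input-oriented, standard frontier, epsilon = two-phase
#> 31 DMU(s); 2 efficient
#>    1    2    3    4    5    6    7    8    9   10   11   12   13   14   15   16
#> 0.96 0.97 0.93 1.00 0.96 0.94 0.91 0.94 0.97 0.97 0.96 0.98 0.98 0.97 0.97 0.96
#>   17   18   19   20   21   22   23   24   25   26   27   28   29   30   31
#> 0.94 0.96 0.92 0.93 0.97 0.96 1.00 0.95 0.97 0.95 0.96 0.95 0.97 0.93 0.88
```

Only batches 4 and 23 span the constant-returns frontier. Batch 31, the
smallest producer, scores 0.88: the frontier (peers `res$benchmarks[["31"]]`
= 4 and 23) could produce its 195 t of chicken with ~12% less of every
input. The composite ranking separates the two efficient batches:

```r
head(composite_efficiency(tab), 4)
#>   dmu standard inverted composed composed_star rank ambiguous
#> 1   4   1.0000   0.9009   0.5495        1.0000    1     FALSE
#> 2  23   1.0000   0.9093   0.5453        0.9923    2     FALSE
#> 3  13   0.9792   0.9103   0.5344        0.9725    3     FALSE
#> 4  12   0.9763   0.9192   0.5285        0.9617    4     FALSE
```

Batch 4 is the benchmark: on the standard frontier *and* farthest from the
worst-practice (inverted) frontier. The indicator panel shows why, and the
gap report turns it into an improvement agenda for everyone else:

```r
ind <- zootech_indicators(tab)    # viability, DWG, FCR, PEF
head(gap_report(ind, composite_efficiency(tab), benchmark_id = 4), 3)
#>   dmu viability   dwg feed_conversion   pef efficiency gap_viability gap_dwg ...
#> 1   4     96.51 76.23           1.502 490.0     1.0000          0.00  0.0000
#> 2  23     96.44 74.73           1.462 493.0     0.9923         -0.07 -1.4985
#> 3  13     93.50 75.44           1.517 464.9     0.9725         -3.01 -0.7861
```

Negative gaps (`worse_*` flags) mark the metrics a batch must work on;
batch 4 combines 96.5% viability, 76 g/day gain and FCR 1.50 with the
sample's lowest unit costs.

`run_report()` drives the whole pipeline (statistics, correlations, four
DEA runs, composite ranking, indicators and gaps) and writes delimited
tables plus a JSON summary; `exec/broilerdea` is a thin command-line
front-end over it. `simulate_farms(n, seed)` generates structurally
realistic farm tables, and `planted_frontier()` builds instances whose true
efficiencies are known in closed form — the solver's validation harness.

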