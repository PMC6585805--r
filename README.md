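# kinomekin

Analysis of time-resolved tyrosine-kinase peptide-array (kinome-profiling)
data. Flow-through arrays such as 144-peptide tyrosine-kinase chips image the
phosphorylation of every peptide spot every few minutes, producing one
intensity–time curve per peptide, technical replicate and condition — for
example, lysates of mesenchymal stromal cells adhering to an
osteoblast-derived extracellular matrix (ECM) versus a titanium surface.
`kinomekin` turns those curves into per-peptide activity calls and
between-condition comparisons.

The core procedure:

* **Windowed V<sub>max</sub>** — the maximal apparent phosphorylation
  velocity is the tangent (OLS slope) of the curve within fixed windows
  after the 640 s reaction start: early 640–1040 s, mid 1040–1440 s,
  late 1440–1840 s. Each peptide's kinetic class is the window with the
  steepest replicate-mean rise. Negative replicate slopes are clipped to
  zero before averaging.
* **Rank-background ("Markov") calling** — per condition the 143 analyte
  peptides are ranked by mean V<sub>max</sub>, a linear background trend is
  fitted to the lowest 60, and a peptide is a positive "on" call when
  mean V<sub>max</sub> − 1.95 × SD exceeds the trend at its rank.
* **Paired AUC comparison** — overall activity per peptide is the
  trapezoidal area under the replicate-mean curve from reaction start;
  shared positive peptides are compared across conditions with an exact
  Wilcoxon matched-pairs signed-rank test.
* **Overlap, classes, enrichment** — Venn partition of the positive sets,
  per-class call counts, peptide→gene collapsing and right-tail
  hypergeometric enrichment against GMT gene sets.
* **Synthetic data** — a generator emulating the statistical structure of a
  two-substrate array run (curve shapes, replicate noise, active/background
  structure) with full ground truth, used to validate sensitivity and
  specificity of the calling rule.

The published per-peptide call table of the ECM-vs-titanium comparison is
shipped as a checksummed fixture (`inst/extdata/published_calls.tsv`);
`reproduce_published_counts()` recomputes its eleven printed summary counts.

## Worked example

```r
library(kinomekin)

sim <- simulate_dataset(sim_config(seed = 1))   # two-condition synthetic run
fit <- kinome_profile(sim$dataset)              # Vmax estimation + calling
summary(fit)
#> Kinome profile of 143 analyte peptides
#> Markov-positive calls per kinetic class:
#>     early mid late total
#> ECM    47  12    5    64
#> Ti     44  10    4    58
#> Overlap (ECM vs Ti): 54 both, 10 ECM-only, 4 Ti-only

compare_conditions(fit)
#> Kinome comparison: ECM vs Ti (pairing: intersection, 54 peptides)
#>   AUC ECM: 1.47e+05 +/- 5.668e+04   AUC Ti: 1.227e+05 +/- 4.508e+04
#>   Wilcoxon signed-rank V = 1485, p = 1.67e-10
#>   Calls: 54 both, 10 ECM-only, 4 Ti-only
```

The summary counts the on-calls per kinetic class and condition (this seed
calls 64 of 143 peptides on ECM, 58 on titanium, 54 shared — the simulation
planted 63/59/55). The comparison pairs the 54 shared positive peptides and
finds significantly higher AUC on ECM, reflecting the simulated 1.25×
activity advantage. `plot(fit)` draws the rank-vs-V<sub>max</sub> diagnostic
with the fitted background trend, and `coef(fit)` returns the peptides ×
conditions V<sub>max</sub> matrix.

Checking the published call-table arithmetic:

```r
report <- reproduce_published_counts()
all(report$pass)          # TRUE: 63/59 calls, 55/8/4 overlap, 43/16/4 and
                          # 37/10/12 class counts all reproduced
```

`run_pipeline(pipeline_config(...))` orchestrates
simulate/read → V<sub>max</sub> → calls → comparison → enrichment with a
reproducibility manifest (seed, settings, md5 checksums of every output).

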