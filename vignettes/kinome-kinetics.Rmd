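---
title: "Windowed Vmax estimation and rank-background activity calling for kinetic peptide arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed Vmax estimation and rank-background activity calling for kinetic peptide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomekin)
```

## The measurement and the model

Flow-through tyrosine-kinase peptide arrays expose 144 consensus peptide
substrates (one of them an internal positive control) to a cell lysate and
image the fluorescently detected phosphorylation of every spot repeatedly
over the run, giving one intensity–time curve per peptide, technical
replicate and condition. The kinase reaction starts at $t = 640$ s; before
that the signal is washing/baseline. Peptide phosphorylation curves fall
into three recognisable shapes:

* **early** — classical saturating kinetics, with the initial slope
  approximating the maximal velocity $V_\max$;
* **mid** — a lag phase followed by a rapid sigmoidal rise
  (Maxwell–Boltzmann-like activation), steepest near the middle of the run;
* **late** — a long lag with the rapid rise only towards the end.

`kinomekin` replaces shape classification by visual inspection with a
deterministic rule. $V_\max$ is estimated as the *tangent* of the curve in
three fixed, contiguous, 400-s windows after reaction start — early
$[640, 1040]$ s, mid $[1040, 1440]$ s, late $[1440, 1840]$ s — and the
kinetic class of a peptide is the window with the steepest replicate-mean
rise (exact ties break toward the earlier window). The tangent is the
ordinary least-squares slope of intensity against time over the readings
inside the closed window; on grids too sparse to put two readings in a
window the slope falls back to the difference quotient of the linearly
interpolated curve between the window edges. Both reduce to the same
tangent on dense, near-linear data. Windows are closed intervals, so a
reading at exactly 1040 s legitimately contributes to both the early and
the mid fit.

Replicate aggregation follows the field's zero-clipping convention:
negative replicate slopes are set to zero *before* averaging, and only
peptides with a positive clipped mean are considered further. The SD across
technical replicates of the class-window slope is the dispersion used by
the calling rule. Classification uses replicate-averaged slopes (one class
per peptide per condition); the replicate-level slopes exist only to supply
the mean and SD. Averaging per-replicate tangents is what the SD-based
calling rule requires; for OLS tangents on a common grid it coincides with
the tangent of the averaged curve.

## The "Markov" on/off calling rule

Despite its historical name, the rule is a rank-based background threshold,
and only that is implemented. Per condition, the 143 analyte peptides are
ranked ascending by mean $V_\max$ (ties broken alphabetically by peptide id
so the ranking is reproducible) and a linear background trend is fitted by
OLS to the lowest 60 peptides. A peptide is *Markov-positive* ("on") when

$$\bar V_\max - 1.95 \, \mathrm{SD}(V_\max) > b(r),$$

where $b(r)$ is the background trend evaluated at the peptide's own rank
$r$. Evaluating at the peptide's own rank follows the rank-vs-$V_\max$
picture in which each peptide is compared against the extrapolated
background at its position; a fixed alternative (the trend value at rank 60
for every peptide) is available via `background_eval = "fixed_rank"`. The
internal positive control (`ART_003_...`) is excluded from all analysis;
the artificial ABL1 substrate (`ART_004_...`) participates like any analyte
peptide, since it appears as a called peptide in the published table. Both
sides of the inequality scale linearly with intensity, so calls are
invariant under intensity rescaling — the rule needs no normalisation
between arrays of different gain.

```{r fit, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1))
fit <- kinome_profile(sim$dataset)
summary(fit)
plot(fit)          # rank vs Vmax with the fitted background trend
```

## Comparing two substrates

Overall kinase activity per peptide is summarised by the trapezoidal area
under the replicate-mean curve from reaction start to the last reading
(AUC, AU·s). Two conditions are compared by pairing the AUCs of peptides
positive in *both* conditions (the default `pairing = "intersection"` —
the only choice under which each member of a pair carries a call; union
and all-peptides pairings are available) and applying the Wilcoxon
matched-pairs signed-rank test. The test discards zero differences,
mid-ranks ties, uses the exact null distribution (computed by convolution
of the rank generating function, valid also under ties) up to 25 effective
pairs and a tie-corrected normal approximation with continuity correction
beyond. Absolute AUC magnitudes depend on the scanner's intensity scale
and are not comparable across instruments; only within-run paired
contrasts are meaningful, which is why the package reports the test and
the ratio rather than targeting any absolute AUC value.

## Gene mapping and enrichment

Consensus peptides covering different phospho-sites of one protein are
collapsed to a single parent gene symbol; the internal control is dropped
and the artificial substrate contributes ABL1. Enrichment of a hit list
against user-supplied GMT gene sets is the right-tail hypergeometric
(one-sided Fisher) probability with a configurable universe size
(default $N = 20000$, the order of the protein-coding genome). This is a
deliberately database-independent stand-in for proprietary pathway tools:
their p-values depend on curated knowledge bases and are not reproduced
here. No multiple-testing correction is applied by default because single
raw enrichment p-values are what such tools report; Benjamini–Hochberg is
available behind `p_adjust = TRUE`. The packaged annotation table
(`peptide_annotation_synthetic.tsv`) is a synthetic reconstruction: gene
symbols for the 67 published called peptides follow standard UniProt
entry-name conventions, and the packaged GMT is likewise a small synthetic
collection for demonstrations and tests.

## What the simulator emulates — and what it does not

No raw fluorescence data for the original two-substrate experiment were
ever deposited, so the package ships a generator that emulates the
*statistical structure* of such a run and carries full ground truth. The
defaults are the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_peptides` | 144 | analytes + 1 internal control |
| `n_replicates` | 3 | technical replicates |
| `time_grid` | 0–1900 s, step 100 s | covers all windows with ≥ 4 readings each |
| `n_active_shared` / `a_only` / `b_only` | 55 / 8 / 4 | the published overlap structure |
| `class_mix` | 0.68 / 0.25 / 0.07 | ≈ the published early/mid/late proportions |
| `effect_ratio` | 1.25 | activity advantage of condition A (ECM) |
| `noise_sd` | 5 AU | ≈ 5% of the typical amplitude |
| `background_level` | 20 AU | flat pre-reaction baseline |
| `amplitude_range` | 50–200 AU | log-uniform, gives a graded Vmax ranking |

Curve templates: early
$A\,(1 - e^{-k (t-640)})$ with $k = \ln(10)/800$ (90% of plateau by
1440 s); mid and late are logistics $A/(1 + e^{-(t - c)/\tau})$ with
$\tau = 100$ s and centres $c = 1240$ and $1640$ s, so the steepest rise
falls at the centre of the respective window. All curves are exactly flat
at `background_level` before 640 s (reactions start at 640 s), and noise is
additive i.i.d. Gaussian, independent across replicates — the simplest
defensible choice given that no noise model was published. The total run
length of 1900 s is an assumption (just past the late window); the
published assay duration is not stated. A 300-s-step "paper-like" grid is
valid configuration and exercises the sparse-window interpolation
fallback.

The generator does **not** model antibody-binding chemistry, washing
artifacts, spatial spot effects, photobleaching, or inter-array gain
differences. Consequently, passing recovery tests show that the
*estimation and calling machinery* is correct under the stated noise
model — not that the rule has these operating characteristics on real
arrays with structured noise.

Under the defaults the tested contracts are: noiseless runs give 100%
kinetic-class recovery, 100% calling sensitivity and zero false positives;
with default noise, sensitivity stays ≥ 0.9 and the false-positive rate
≤ 0.05 across 50 seeds; and with the 1.25× effect the paired signed-rank
test over shared positives is significant at 0.05 in ≥ 95 of 100 seeds.
These thresholds are contracts of this package's simulation, not published
claims. Problem sizes in the test-suite (10–100 seeds of a
144 × 3 × 2 × 20-reading array) keep a full run well under a minute while
making the binomial noise on the estimated rates small against the
thresholds.

## Numerical choices and degenerate inputs

* OLS slopes and trends use the closed-form centred formulation; all
  orderings use C-locale (radix) sorting so results do not depend on the
  session locale.
* Zero clipping happens per replicate *before* averaging (clip, then
  "average above zero" — the published order of operations).
* Vmax ties in ranking break alphabetically by peptide id; window ties in
  classification break toward the earlier window.
* An all-zero-difference AUC pairing yields a degenerate signed-rank
  result with $p = 1$ rather than an error.
* `curve_auc` linearly interpolates the curve at `from_time` when it falls
  between readings, keeping the integral additive across subintervals.
* Written call tables are rounded to 12 significant digits and row-ordered
  deterministically, so identical analyses produce byte-identical files.
* The published call-table fixture is md5-checksummed at load time.

## Known limitations

* The background-trend fit assumes at least `n_background` genuinely
  quiescent peptides per condition; arrays where most peptides are active
  would bias the trend upward and cost sensitivity.
* One call per peptide per condition: per-class rankings are deliberately
  not implemented, matching the published one-call-per-substrate layout.
* Between-run AUC magnitudes are instrument-scale dependent; only paired
  within-run comparisons are supported.
* The enrichment stand-in treats gene sets as unstructured sets; pathway
  topology, directionality and curated activation states are out of scope.
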