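# tissueqc

Detect tissue heterogeneity in gene expression data.

Bulk expression profiles often contain signal from cells that do not belong
to the target tissue of profiling — infiltrating immune cells, dissection
carry-over from adjacent tissue, contamination, or plain mislabeling. Left
undetected, such heterogeneity injects contaminant-specific genes into
downstream differential-expression results and undermines reproducibility.
`tissueqc` is a first-line, single-sample QC tool for anyone analysing bulk
(or pseudo-bulk) transcriptomics: it scores a collection of *tissue
signatures* — sets of genes preferentially expressed in one or few tissues —
against every sample and flags samples where the wrong tissue lights up.

## The method

For each sample the profile of m genes is ranked once (midranks for ties);
each signature of n1 genes is then tested with the tie-corrected,
continuity-corrected normal approximation of the one-sided
Wilcoxon-Mann-Whitney rank-sum test of

U = R1 − n1(n1+1)/2,  E[U] = n1·n2/2,
Var[U] = (n1·n2/12)·((m+1) − Σ(t³−t)/(m(m−1))),

where R1 is the signature's midrank sum and t the tie-group sizes. The
enrichment score is |log10 p| (0 = no enrichment; 3 means p = 10⁻³;
unbounded above), computed in log space so extreme enrichment stays finite.
Ranking once and evaluating all signatures from the precomputed ranks via a
sparse membership-indicator product makes scoring s sets cost
O(m log m + Σ|set|) per profile instead of O(s·m log m); the results are
numerically identical to R's native `wilcox.test` (asserted to 1e-12 in the
tests).

The package also:

- derives tissue signatures from a tissue-profiled compendium via the Gini
  index rule (G ≥ 0.7 and expression among the tissue's top 3), with
  replicate averaging and additive batch merging (`derive_signatures`,
  `average_replicates`, `merge_batches`);
- ships two seeded simulation frameworks: spiked N(μ,1) signatures on an
  N(0,1) background (`sensitivity_curve`) and convex mixing of two tissue
  profiles Y = ωY_A + (1−ω)Y_B (`mixing_grid`, `detection_threshold`);
- reads/writes GMT, TSV and GCT 1.2, and exposes everything through the
  `exec/tissueqc` command line (`run`, `derive-signatures`, `gini`,
  `simulate-sensitivity`, `simulate-mix`, `make-fixtures`).

## Worked example

Generate a small synthetic dataset with known ground truth — 500 genes,
8 samples from 3 tissues with disjoint signatures, where sample
`kidney_mix` is a planted 70/30 kidney/pancreas mixture — and score it:

```r
library(tissueqc)
fx   <- make_fixtures("demo", seed = 0)
expr <- read_expression(fx$expr)
sets <- read_gmt(fx$gmt)
res  <- score_gene_sets(expr, sets)
round(res$scores, 2)
#>          kidney_1 kidney_2 kidney_3 kidney_mix pancreas_1 pancreas_2 heart_1 heart_2
#> kidney      11.39    10.98    11.03       8.07       0.26       0.24    0.24    0.19
#> pancreas     0.29     0.25     0.33      12.79      16.33      16.30    0.25    0.30
#> heart        0.07     0.09     0.07       0.05       0.08       0.11   12.85   13.05
```

Every pure sample scores highest for its own tissue (scores ≈ 11–16, i.e.
p ≈ 10⁻¹¹–10⁻¹⁶), while decoy signatures stay near 0. In `kidney_mix` the
pancreas signature (12.79) outscores kidney (8.07): the 30% pancreas
fraction, whose enzyme-like signature genes are very highly expressed,
dominates the sample — exactly the warning a contaminated sample should
raise. The same check from the shell, with a per-sample report:

```sh
tissueqc run --expr demo/expr.tsv --gmt demo/signatures.gmt \
  --out scores.tsv --target-tissue kidney --report report.json
# WARNING sample kidney_mix: signature(s) outscoring target 'kidney': pancreas
```

How much signal does the test need? The spiked-signature simulation (22000
N(0,1) background genes, one 43-gene signature shifted to N(μ,1), scored
against 154 random decoy signatures, 10 samples per μ):

```r
curve <- sensitivity_curve(c(0, 0.5, 1, 2, 3), seed = 0)
aggregate(cbind(score, rank) ~ mu, curve, mean)
#>    mu      score rank
#> 1 0.0  0.5301696   74
#> 2 0.5  2.8163461    2
#> 3 1.0  9.4988460    1
#> 4 2.0 20.9838363    1
#> 5 3.0 27.4129889    1
```

At μ = 0 the spiked set behaves like any decoy (mean rank 74 of 155); from
μ = 1 — one standard deviation of mean elevation — it ranks first in every
sample.

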