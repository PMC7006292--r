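# ndcrank

Ranking **nonlinearly expressed genes** in binary-phenotype expression
matrices with the **normalized differential correlation (NDC)**.

## What problem this solves

Differential-expression screens built on linear contrasts (t-test, count
models) rank genes by a mean shift between two classes — say tumor versus
adjacent normal tissue. They systematically miss genes whose expression is
strongly *informative* about the class without a mean shift: the classic
case is a gene whose expression in one class splits into low and high modes
flanking the other class's single mode, so the class means coincide, the
t-test p-value is large, and the gene is discarded — even though mid-range
expression almost surely means one class and extreme expression the other.
`ndcrank` is for transcriptomics analysts who want to surface exactly those
genes from a genes-by-samples matrix (e.g. a UCSC Xena genomicMatrix of
TCGA level-3 data) plus a two-column sample/label file.

## The statistic

For one gene `x` against binary phenotype `y`:

```
NDC(x, y) = ( MIC(x, y) − R²(x, y) − Thre_MIC ) / |R(x, y)|
```

* `MIC` — maximal information coefficient, estimated exactly for the binary
  case by dynamic programming over x-axis partitions (grid budget
  `n^0.6`, cuts never split tied values, invariant to monotone transforms);
* `R`, `R²` — point-biserial correlation and determination coefficient, the
  linear part of the association;
* `Thre_MIC` — the 95% nearest-rank fractile of MIC over
  gene-draw-and-shuffle permutations (default 1000), a finite-sample
  significance floor.

Large positive NDC means "strongly associated with the phenotype, but not
linearly". Genes are ranked by NDC, then the top 1000 are re-sorted by MIC
(`rank_final`). The package also provides the Welch-t and Yates-corrected
chi-square comparators, a Xena-dialect reader/writer, and a synthetic
cohort generator that plants null, linearly shifted, bimodal and
four-level-stratified genes with ground truth.

## Worked example

```r
library(ndcrank)

# 200-gene cohort, 60 tumor + 60 normal samples: 5 planted bimodal genes,
# 10 planted linear genes, 185 nulls
sim <- simulate_expression(60, recovery_specs(200, n_bimodal = 5, n_linear = 10),
                           seed = 1)
res <- ndc_rank(sim$mat, sim$labels, n_perm = 1000, seed = 1, top_pool = 100)

res$null$threshold
#> [1] 0.2714
head(res$scores[order(res$scores$rank_final), ], 8)
#>  gene_id    mic       r     r2     ndc rank_ndc rank_final
#>     g003 1.0000 -0.0212 0.0005 34.3072        1          1
#>     g004 1.0000 -0.0363 0.0013 20.0623        2          2
#>     g002 1.0000 -0.0969 0.0094  7.4243        3          3
#>     g001 1.0000  0.1036 0.0107  6.9278        4          4
#>     g011 1.0000  0.8742 0.7642 -0.0407       17          5
#>     g009 0.9730  0.8675 0.7526 -0.0589       20          6
#>     g005 0.9541 -0.1128 0.0127  5.9403        5          7
#>     g008 0.9425  0.8409 0.7071 -0.0429       18          8
```

All five planted bimodal genes (`g001`–`g005`) reach the head of the list:
their MIC is at or near 1 (expression separates the classes almost
perfectly once partitioned) while `|r| ≈ 0.02–0.11`, so their NDC is large
and positive. The planted linear genes (`g008`, `g009`, `g011`) carry high
MIC too but also `r² ≈ 0.7–0.76`, which drives their NDC slightly negative
— they are what a t-test would find anyway. The permutation threshold
(0.2714 here) is what a null gene's MIC can reach by chance at this sample
size: null genes' numerators are negative ~95% of the time and their small
`|r|` amplifies the negativity, pushing them down the list.

The contingency-table utility reproduces printed tumor-grade associations
from their counts:

```r
chi2_yates(16, 10, 10, 29)
#> statistic = 6.9471, p = 0.0084
```

A command-line front end wrapping these functions (subcommands `rank`,
`threshold`, `mic`, `simulate`, `chi2`) is in `inst/cli/ndc.R`:

```sh
Rscript inst/cli/ndc.R simulate --patients 60 --seed 1 --out-prefix demo
Rscript inst/cli/ndc.R rank --expr demo_matrix.tsv --labels demo_labels.tsv \
    --out demo_ranked.tsv --perms 1000 --seed 1
```

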