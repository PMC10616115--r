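# pureR

Upstream-regulator inference from differential expression and a signed
chemical–gene interaction knowledge base.

## The problem

Many phenotypes are caused by exposure to — or deficiency of — a chemical,
drug, or toxicant (CDT): a glucocorticoid treatment, an endocrine disruptor,
a missing micronutrient. Given only a differential-expression (DE) profile
comparing the phenotype with a control, which CDT is responsible? And for
drug repurposing, the mirror question: which drug's known effects would
*revert* the disease signature?

`pureR` implements **PURE** (Predicting Upstream REgulators), an edge-level
causal-analysis method that answers both questions, together with reference
implementations of five standard comparator methods, the benchmarking
conventions used to evaluate them, and a synthetic-data generator for
recovery experiments. It is aimed at computational biologists working with
CTD-style chemical–gene interaction tables (Comparative Toxicogenomics
Database `chem_gene_ixns` exports) and standard DE tables (gene, log
fold-change, p-value).

## The method

The knowledge base is a set of signed edges `e(c, g)`: CDT `c` *activates*
(`s(e) = +1`) or *inhibits* (`s(e) = −1`) the expression of gene `g`. DE
genes are selected at `|log(FC)| > 0.6` and `p < 0.05` (strict) and carry
the sign of their fold-change, `s(g)`.

For every CDT, two directional hypotheses are tested:

- **H1** — the CDT is present/overabundant in the phenotype;
- **H2** — the CDT is lacking/absent.

Restricting the knowledge base to DE genes gives the overlap edge set `E`.
An edge supports H1 when `s(e) = s(g)` (an activation edge onto an
up-regulated gene, or an inhibition edge onto a down-regulated one), and
supports H2 otherwise — the two sets partition `E`. For a focal CDT the
2×2 edge contingency table

|                  | supports H1 | against H1 |
|------------------|-------------|------------|
| edges of `c`     | `l`         | `k`        |
| edges of others  | `m`         | `n`        |

is scored with the one-sided Fisher exact test,

```
p = sum over tables with first cell >= l of  C(l+k, l) C(m+n, m) / C(‖E‖, l+m)
```

and the H2 p-value is the same test on the column-swapped table
(`p_h2(l,k,m,n) = p_h1(k,l,n,m)`). P-values are Benjamini–Hochberg
corrected per hypothesis family; CDTs are ranked by adjusted p (ties broken
by raw p, then averaged) and called **present** (H1 FDR ≤ 0.05),
**absent** (H2 FDR ≤ 0.05), or **both**.

Because the test counts *edges* rather than genes, a CDT with many
consistently-signed associations accumulates evidence even when the DE list
is short — the regime where gene-level Fisher tests lose power.

Comparators implemented on the same inputs: hypergeometric
over-representation (ORA), two-sample Kolmogorov–Smirnov and Wilcoxon
rank-sum on fold-change scores, classic permutation preranked GSEA, and an
IPA-style activation z-score `z = Σ w·s_R·s_D / sqrt(Σ w²)` with overlap
p-value (calls at `|z| ≥ 2`).

## Worked example

Simulate a 50-CDT knowledge base, perturb `CDT01` (its targets respond in
the direction its edges imply), and ask PURE who did it:

```r
library(pureR)

cfg <- sim_config(seed = 7)          # 50 CDTs, 200 genes, 5-20 edges each
kb  <- generate_kb(cfg)
de  <- generate_profile(kb, true_cdt = "CDT01", cfg)

res <- pure_test(kb, de)
print(res, n = 4)
#> PURE upstream-regulator test: 35 CDTs over 74 overlap edges (44 H1 / 30 H2)
#> Significant at FDR <= 0.05: 1 (present 1, absent 0, both 0)
#>
#> # A tibble: 35 × 14
#>   cdt_id cdt_name n_edges     l     k     m     n     p_h1  fdr_h1 rank_h1  p_h2
#>   <chr>  <chr>      <int> <int> <int> <int> <int>    <dbl>   <dbl>   <dbl> <dbl>
#> 1 CDT01  CDT01         14    14     0    30    30 0.000252 0.00882       1 1.000
#> 2 CDT11  CDT11          3     1     2    43    28 0.937    1            21 0.358
#> 3 CDT15  CDT15          2     0     2    44    28 1        1            35 0.161
#> 4 CDT17  CDT17          1     0     1    44    29 1.000    1            28 0.405
```

All 14 of `CDT01`'s overlap edges support H1 (`l = 14, k = 0`), its H1
Fisher p-value is 2.5e-4 (FDR 0.0088), and it is the only CDT called:
PURE reports the planted regulator at rank 1 with zero false positives.
`tidy()`, `glance()` and `autoplot()` give the table, the one-row summary
and the H1-vs-H2 evidence plot; `run_method()` produces the comparable
ranked report for any of the seven methods, and `rank_of_true()` /
`aggregate_evaluations()` turn reports into benchmark summaries.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pure.R simulate --out-dir sim --seed 5
Rscript inst/cli/pure.R run --kb sim/kb.tsv --de sim/de.tsv --out results.tsv
Rscript inst/cli/pure.R benchmark --manifest experiments.yaml --out-dir bench
```

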