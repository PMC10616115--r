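---
title: "Edge-level causal analysis of upstream regulators: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-level causal analysis of upstream regulators: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pureR)
```

This vignette explains the statistical model behind `pureR`, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where more than one defensible
option existed.

## The model

A chemical–gene knowledge base is a set of signed edges: CDT $c$ activates
($s(e_{c,g}) = +1$) or inhibits ($-1$) the expression of gene $g$. Only
direct expression-changing associations qualify; abundance, methylation,
activity and similar interaction types carry no expression direction and
are excluded at parse time, as are direction-less `affects^expression`
rows (counted and reported to the user). A CDT that both increases and
decreases the same gene's expression keeps two opposite-sign edges: the
test below counts edges, not genes, so each contributes to its own tally.

Given DE genes with signs $s(g)$, the overlap network restricts the
knowledge base to edges whose target is DE. Each edge supports hypothesis
H1 (CDT elevated) iff $s(e) = s(g)$, otherwise H2 (CDT lacking); the two
sets partition the overlap edges. Per CDT, the edge contingency table
$(l, k, m, n)$ — own supporting / own opposing / others' supporting /
others' opposing — is scored with the one-sided Fisher exact test: the sum
of hypergeometric table probabilities
$\binom{l+k}{l}\binom{m+n}{m}/\binom{\lVert E\rVert}{l+m}$ over all tables
with first cell $\ge l$ at fixed margins. The H2 p-value is the same test
after swapping the table's columns, an exact involution. Benjamini–
Hochberg correction is applied and CDTs are called present / absent /
both at FDR $\le 0.05$ (inclusive).

The null hypothesis is that the focal CDT's edges are an exchangeable
sample from the overlap edges with respect to hypothesis support; the test
asks whether its support is improbably concentrated. Assumptions worth
keeping in mind: edges are treated as independent pieces of evidence
(curation redundancy violates this), all edges have equal weight
(the weight field exists for weighted sources but CTD provides none), and
the background is the overlap network itself, so heavily annotated CDTs
shape the margins for everyone.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `logfc_cut` | 0.6 | DE selection, strict `|log FC| >` (log base is the caller's; the cutoff applies to values as given) |
| `p_cut` | 0.05 | DE selection, strict `p <` (raw vs adjusted is caller metadata; the filter is agnostic) |
| `alpha` | 0.05 | FDR call threshold, inclusive `<=` |
| `fdr` | `by_hypothesis` | BH family: per hypothesis, or `pooled` over both |
| `tail` | `inclusive` | Fisher tail; `strict` excludes the observed table |
| `min_edges` | 0 | every CDT is tested regardless of edge count |
| `tiebreak_raw_p` | `TRUE` | break adjusted-p ties by raw p before average ranks |

Boundary values are excluded by the strict DE inequalities, so a gene at
exactly `|log FC| = 0.6` or `p = 0.05` never flips a result between runs
of tools that disagree about `>=` vs `>`.

## Design choices

**Inclusive Fisher tail.** The upper tail includes the observed table,
$P[X \ge l]$. An exclusive tail would assign p = 0 to a maximal table,
which is not a valid p-value; the `strict` mode exists only for
sensitivity analysis.

**FDR families.** H1 and H2 p-values are corrected separately by default:
each research hypothesis defines its own family of tests over the same
CDTs, and pooling would let strong evidence under one hypothesis dilute
the correction of the other. The pooled mode is available for users who
prefer a single global error rate.

**Tie-breaking in ranks.** CDTs are ranked by FDR-adjusted p-value, the
statistic used for significance calls. BH adjustment is a step-up
procedure that flattens long stretches of the sorted p-values onto a
common value — in small overlap networks most adjusted values saturate at
1 — so ranking on the adjusted value alone collapses genuinely different
evidence into massive ties. The default therefore breaks adjusted-value
ties by the raw p-value before applying the average-rank convention; CDTs
tied on both values still share an average rank. Setting
`tiebreak_raw_p = FALSE` ranks on adjusted values only.

**Both-calls are reported.** A CDT significant under H1 and H2
simultaneously is biologically awkward but statistically well-defined
(the two one-sided tests are separate hypotheses); it is reported with
call `both` rather than suppressed.

**IPA-style overlap p-value.** The gene-wise overlap statistic is the
one-sided Fisher upper tail written as a factorial sum over tables
reachable by shifting mass into the overlap cell. The sum's natural upper
limit is $\min(b, c)$ — beyond it the factorial terms vanish because a
reciprocal factorial of a negative integer is zero — and with that limit
the sum equals the exhaustive upper-tail enumeration on every margin
(verified to $10^{-12}$ in the tests). The least extreme observation
($a = 0$) then correctly yields p = 1.

**GSEA as classic permutation.** The preranked enrichment score uses the
weighted Kolmogorov–Smirnov running sum with weight exponent 1, and
significance comes from `nperm` gene-label permutations (default $10^4$,
`minSize` 15) with the +1-corrected permutation p-value. Adaptive
multilevel p-value estimators are deliberately out of scope: the
permutation form is the defined, desk-verifiable computation, and the
enrichment score itself is cross-checked against `fgsea::calcGseaStat` in
the test suite. Gene sets below `min_size` are reported `not_tested` with
`NA` statistics rather than dropped, so downstream rank imputation can see
them.

**Cross-method Wilcoxon comparisons.** Whether benchmark rank vectors
should be compared paired or unpaired, exact or approximate, is a
judgement call; both variants are implemented and reported. The exact
paths enumerate the full permutation distribution (group assignments, or
sign flips of non-zero differences), which stays valid under ties —
`stats::wilcox.test` has no exact path there — and identical paired
vectors yield p = 1 by convention. The benchmark CLI prints both variants
rather than privileging one.

**KS/Wilcoxon group membership.** "DEhit" is the set of DE genes targeted
by the CDT, compared against all remaining DE genes, on log fold-change
scores. Both tests see fold-change signs but are blind to edge signs, so
they cannot distinguish H1 from H2 — the property the metamorphic tests
assert.

## The synthetic-data generator

`sim_config()` describes the generative story the test assumes: one
perturbed CDT whose targets respond in the direction its edges imply
(H1), or against it (H2), plus unrelated background DE. Defaults — 50
CDTs, 200 genes, 5–20 edges per CDT, half activating, agreement noise 0,
background DE rate 0.02 — give a compact universe in which a planted CDT
with noiseless response is recoverable at rank 1, while noise levels up to
0.5 degrade recovery smoothly (each target's sign flips independently with
the noise probability; at 0.5 the signal is gone by construction).

DE magnitudes are drawn as `logfc_cut` plus a log-normal excess
(`meanlog` 0, `sdlog` 0.5, i.e. a typical DE gene at |log FC| ≈ 1.6), DE
p-values as `p_cut ×` Beta(1, 4), non-DE genes uniform inside the
complementary boxes — so the generated profile partitions *exactly* at the
selection thresholds and no test outcome ever hinges on boundary
handling. Replicate `r` of a recovery experiment derives its seed as
`seed + r`, making any single replicate reproducible in isolation.

What the generator does **not** emulate: correlated expression between
co-targeted genes, curation redundancy (several edges restating one
finding), annotation bias toward well-studied chemicals, gene-level
measurement error, or realistic p-value/fold-change joint distributions.
Passing recovery tests therefore demonstrate the statistical machinery is
correct under its own assumptions — not that real CTD + GEO analyses will
rank true CDTs as cleanly.

## Problem sizes and numerical notes

The test suite verifies the Fisher and overlap tails against exhaustive
enumeration of every 2×2 table with total at most 60, the recovery
property over 50 replicates at noise 0 and 50 per level over the noise
grid 0–0.5, and the invariants (partition, swap duality, sign-flip
symmetry, rank-sum conservation, BH monotonicity) over batches of
simulated networks — sizes at which the whole suite completes in about a
minute and a half on a laptop-class core while still exercising the full
combinatorial space of small tables.

All tail sums are computed in log space (`lchoose` / `lfactorial`) and
exponentiated per term, accurate to ~1e-15 for the table sizes of
interest; the ORA upper tail is summed directly rather than through the
`1 − P(X ≤ x−1)` complement, which cancels catastrophically when the tail
is tiny. Serialized outputs round to 6 significant digits so repeated
runs diff cleanly; in-memory values are never rounded.

## Known limitations

- Only direct CDT→gene edges are scored; no propagation through gene–gene
  networks, chemical-family hierarchies, or CDT–disease relations.
- The method inherits the knowledge base's ascertainment: poorly
  annotated CDTs cannot accumulate enough edges to reach significance.
- The DE threshold convention is fixed at selection time; the test sees
  only the signed DE gene list, so a threshold choice upstream changes
  the overlap network silently.
- H2 calls identify signature reversal candidates, a first computational
  step for repurposing — not evidence of clinical efficacy.
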