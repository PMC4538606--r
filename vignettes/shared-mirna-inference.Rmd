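---
title: "Inferring lncRNA-disease associations from shared miRNA partners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-disease associations from shared miRNA partners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hglda)
```

## The problem

Experimentally verified lncRNA-disease associations are scarce — a few
hundred high-quality pairs — while miRNA-disease associations and
lncRNA-miRNA interactions number in the thousands.  Because lncRNAs act in
part by titrating miRNAs, a lncRNA and a disease that share unexpectedly
many common miRNA partners are plausible association candidates.  This
package turns that observation into two tools:

* a **prediction model**: a hypergeometric enrichment test on every
  lncRNA-disease pair, requiring *no* known lncRNA-disease association;
* a **similarity model**: large-scale lncRNA functional similarity obtained
  by cascading disease semantic similarity through the two association
  layers.

## The enrichment model

Let $N$ be the number of distinct miRNAs associated with any lncRNA or
disease in the inputs (the pooled universe), $M$ the number interacting
with a given lncRNA, $L$ the number associated with a given disease, and
$x$ the number shared.  Under the null that the disease's $L$ partners are
a uniform draw without replacement from the universe, the shared count is
hypergeometric, and the pair's score is the inclusive upper tail

$$P = \sum_{k \ge x} \frac{\binom{M}{k}\binom{N-M}{L-k}}{\binom{N}{L}}.$$

The inclusive tail $P(X \ge x)$ is the standard enrichment convention; it
makes $x = 0$ give exactly 1, so pairs whose lncRNA or disease has no
miRNA partner are retained with $P = 1$ rather than dropped, keeping the
score table a complete cross-product for downstream ranking.  A strict
tail $P(X > x)$ is available through `tail = "gt"` for sensitivity
analysis.  The tail is evaluated with `stats::phyper()`, which works with
log-space binomial coefficients and is numerically safe for universes far
larger than the few hundred miRNAs typical here.

All $|\text{lncRNA}| \times |\text{disease}|$ P-values are adjusted
jointly (one family, not per disease) by the Benjamini-Hochberg step-up
procedure, and pairs with FDR strictly below 0.05 are called candidate
associations.  Within one disease, predictions are ranked by ascending
P-value with ties broken by larger shared count $x$, then lexicographic
label, so ranks are deterministic.

Before scoring, miRNA genomic copies producing the same mature miRNA
(`hsa-mir-125b-1`, `hsa-mir-125b-2`) are merged: a trailing `-<digit>`
copy suffix is stripped when the remaining stem ends like a mature name
(so `hsa-mir-7-1` merges to `hsa-mir-7` while `hsa-mir-21` and
`hsa-mir-1` are untouched).  The rule is a regular expression and can be
replaced or disabled.  Entity labels are reconciled across source
databases by trimming, case-folding and whitespace-collapsing, with an
optional user-supplied alias table for residual synonyms — name
reconciliation across databases is inherently lossy, and residual
mismatches shrink the evaluable gold standard rather than corrupt it.

## Evaluation protocol

Each verified lncRNA-disease pair is left out in turn as a test sample
and ranked, by ascending P-value, against the candidate pairs — all
scored pairs with no verification evidence.  The other verified pairs are
excluded from the candidate pool (they *do* have evidence).  Because the
scorer uses no gold information, leaving a pair out does not change any
score, and the loop is implemented as ranking each positive once against
the fixed candidate pool; the result is identical to a literal per-fold
rerun.  Sweeping a rank threshold yields TPR and FPR; the ROC curve is
anchored at $(0,0)$ and $(1,1)$ and the AUC is its trapezoidal area,
which equals the Mann-Whitney concordance with ties counted one half —
the package computes it both ways and the tests require the two routes to
agree to $10^{-9}$.  A `per_disease` mode ranks each test pair only
against its own disease's candidates as a sensitivity analysis; it
reports ranks and the mean concordance but no pooled ROC curve, since
per-disease candidate pools differ in size.

## The functional-similarity cascade

**Disease semantic similarity (S1).**  Each disease is located at one or
more MeSH terms; its DAG is those terms plus all ancestors.  The
disease's own terms contribute 1 and an ancestor contributes
$\Delta \cdot \max(\text{children's contributions})$, so contributions
decay geometrically with distance and a node reached along several paths
keeps the maximum.  Multiple tree positions are merged into one DAG (the
max keeps contributions $\le 1$ and the recursion well defined).  With
$DV$ the sum of a DAG's contributions, two diseases' similarity is

$$S1(A, B) = \frac{\sum_{t \in T_A \cap T_B} \left[D_A(t) + D_B(t)\right]}{DV_A + DV_B},$$

which is 1 for identical DAGs and 0 for disjoint ones.  The decay factor
defaults to $\Delta = 0.5$, the customary value for this DAG-contribution
similarity, and is exposed as a parameter; results vary smoothly in it.
Diseases without a MeSH mapping are excluded from the matrix with a
warning rather than kept as zero rows, which would silently deflate every
group similarity built on top.

**miRNA functional similarity (S2)** is the best-match average of the two
miRNAs' disease groups over S1: each disease in one group is matched to
its most similar disease in the other group, and the best-match scores of
both directions are averaged,

$$S2(u, v) = \frac{\sum_{d \in D(u)} \max_{d' \in D(v)} S1(d, d')
           + \sum_{d' \in D(v)} \max_{d \in D(u)} S1(d, d')}{|D(u)| + |D(v)|}.$$

**lncRNA functional similarity (FS)** applies the same best-match average
to the lncRNAs' miRNA groups over S2.  Group members missing from the
base matrix are dropped (with a logged count) instead of being imputed as
zero-similarity rows, and entities whose group becomes empty are excluded
— the method is undefined for lncRNAs without known miRNA partners.  The
diagonal is forced to exactly 1 (the formula gives 1 for identical
groups; forcing removes float drift).  An empty group makes a pairwise
similarity undefined and is reported as `NA`, never 0.

The cascade is biased toward entities with many annotations: lncRNAs with
more miRNA partners, and miRNAs whose diseases are well covered by the
ontology, get better-resolved similarities.  This is inherent to
group-based best-match averaging, not a numerical artifact.

## Synthetic data and what the tests show

`fixture_spec()` / `generate_bipartite_fixture()` emulate the three
association tables: two independent Erdős–Rényi bipartite layers at a
background edge density, plus *planted* lncRNA-disease pairs wired to a
common random set of miRNAs, which are emitted as the gold standard.
Defaults are fixed once at 50 miRNAs, 20 lncRNAs, 15 diseases, background
density 0.05 and plants sharing 10 miRNAs: a deliberately small network
whose entity ratios (more lncRNAs than diseases, a shared miRNA layer an
order of magnitude denser than the planted signal) mirror the real
corpora while keeping a 100-replicate recovery study fast.
`generate_dag_fixture()` supplies a complete rooted term tree with
diseases mapped to random leaves for the semantics side.  All draws come
from one local seeded stream; the caller's RNG state is untouched and
outputs are reproducible bit for bit.

The generator draws background edges independently, so it does not
reproduce the degree heterogeneity, annotation bias or correlated
evidence of real curated databases.  Passing the recovery tests therefore
shows that the statistics behave as specified under a known null with a
known planted signal — not that any particular biological database will
yield a particular AUC.  Running the pipeline on real corpora requires
supplying the curated tables through the same TSV interface.

## Numerical and design choices

* Hypergeometric tails via `phyper` (log-space); BH via `p.adjust`.  The
  test suite checks both against independent brute-force oracles
  (exhaustive draw enumeration for every parameter set with $N \le 12$;
  the textbook step-up formula on 1000 random vectors).
* DAG contributions are computed by resolving, in passes, every node
  whose in-DAG children are all resolved — a topological relaxation that
  needs no explicit sort; an independent shortest-path oracle
  ($\Delta^{\text{shortest distance to an own term}}$) verifies it on
  random DAGs.
* Significance uses a *strict* `fdr < threshold` comparison.
* Ties: midranks everywhere (Mann-Whitney one-half convention); ranking
  tie-breaks are `pvalue`, then larger `x`, then label.
* Degenerate inputs fail loudly: empty tables, empty miRNA universes,
  cyclic term graphs (one concrete cycle is named), gold pairs missing
  from the score table (listed by name).

## Limitations

Predictions are only as complete as the miRNA layer: a lncRNA with no
miRNA interactions can never be prioritized, and diseases absent from the
miRNA-disease table are never scored.  The model treats all associations
as equally reliable, ignores evidence weights, and the joint FDR family
means adding diseases changes every adjusted value.  The similarity
cascade inherits ontology coverage: diseases without MeSH terms drop out
of S1 and propagate exclusions upward.
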