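---
title: "Identifying immune-checkpoint-related lncRNAs: models and methods"
author: "icplnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying immune-checkpoint-related lncRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Immune checkpoint (ICP) genes — PD-1, PD-L1, CTLA-4 and their relatives —
modulate the activation of tumor-infiltrating immune cells and are the
targets of checkpoint-inhibitor therapy. Long non-coding RNAs participate in
the same regulatory programs, but which lncRNAs are functionally tied to the
checkpoint axis in a given tumor type is not directly observable. `icplnc`
prioritizes such lncRNAs from bulk expression profiles in four stages, each
of which is a standard, auditable statistic rather than a black box.

A persistent obstacle in bulk tumor data is **tumor purity**: the fraction of
malignant cells in a sample. Immune genes co-vary strongly with purity, so
two transcripts can appear tightly co-expressed merely because both track the
immune cell content of the sample. The framework addresses this by using raw
co-expression only for candidate discovery (stages 1–3) and switching to
purity-adjusted partial correlation for the pathway-level evidence (stage 4).

## The four stages

### 1. ICP-anchored co-expression network

For every candidate pair named in a caller-supplied interaction list
(lncRNA–gene pairs, plus protein–protein interaction pairs touching an ICP
gene), the Pearson correlation is computed on pairwise-complete samples, with
the two-sided p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
freedom. P-values are Benjamini–Hochberg adjusted over all tested pairs
jointly and an edge is kept when $p_{adj} < \alpha$ (default 0.05), with an
optional $|r|$ floor (default 0, since the selection criterion is stated in
terms of adjusted significance alone).

Edge weights are $|r|$: the downstream random walk requires non-negative
weights, and taking the absolute value is the minimal repair that preserves
the strength of association; the signed coefficient is retained as an edge
attribute. ICP–ICP edges from the PPI input are kept by default
(`keep_icp_icp`), as the propagation benefits from connectivity among seeds.

### 2. Personalized PageRank propagation

Influence flows from the ICP genes over the weighted, undirected network via
a random walk with restart: at each step the walker either follows an edge
(probability $d = 0.85$) chosen proportionally to edge weight, or teleports
to an ICP seed chosen uniformly. The implementation is a power iteration on
the row-normalized transition matrix with the conventional treatment of
dangling nodes (their mass teleports to the seed distribution), an L1
convergence tolerance of $10^{-6}$ and at most 100 iterations — the
published defaults of the propagation stage. Non-convergence returns the last
iterate with `converged = FALSE` and a warning rather than an error, matching
the behavior of the graph libraries this stage emulates.

The top $k = 200$ lncRNAs by influence score are carried forward, ties broken
by lexicographic id so runs are reproducible. One deliberate refinement:
**lncRNAs with zero influence score are never returned**. A zero score means
the node is unreachable from every seed (it sits in a component disconnected
from the ICP genes), and padding the "top ICP-related lncRNAs" list with
unreachable nodes would contradict what the propagation score measures. On
realistic connected graphs with more than $k$ reachable lncRNAs this changes
nothing; on sparse graphs it prevents nonsense candidates (in the synthetic
world, purity-confounded lncRNA–gene islands) from free-riding into stage 4.

### 3. Purity-adjusted ranking

For each candidate lncRNA $L$ and every protein-coding gene $G$, the
first-order partial correlation given purity $P$ is

$$PCC = \frac{R_{LG} - R_{LP} R_{GP}}
             {\sqrt{1 - R_{LP}^2}\,\sqrt{1 - R_{GP}^2}},$$

with the two-sided p-value from $t = PCC\sqrt{(n-3)/(1-PCC^2)}$ on $n-3$
degrees of freedom. Genes are ranked by the rank score

$$RS = -\log_{10}(p) \cdot \mathrm{sign}(PCC),$$

where $\log_{10}$ is the standard reading of the "lg" in this score and p is
floored at $10^{-300}$ so the log stays finite. Ties in RS are broken by gene
id ascending.

The ranked universe defaults to protein-coding genes only
(`rank_universe = "genes"`): the immune pathways below contain genes, so
ranking other lncRNAs alongside them would only insert guaranteed misses that
dilute the enrichment statistic. `rank_universe = "all"` is available for
the literal reading.

### 4. Enrichment and the lncRES score

Each immune pathway (a GMT gene set) is tested against the ranked list with
the classic pre-ranked GSEA running sum: hits increment by
$|RS|^{exponent}/\sum_{hits}|RS|^{exponent}$ (exponent 1 by default), misses
decrement by $1/(N - |S|)$, and ES is the signed maximum deviation, in
$[-1, 1]$.

The null distribution is **gene-label permutation**: `n_perm = 1000` random
sets of the same effective size drawn from the ranked universe. The p-value
is one-tailed on the observed sign with a +1 pseudocount,

$$p = \frac{1 + \#\{\text{null}: \text{same sign},\ |ES_{null}| \ge |ES|\}}
           {1 + \#\{\text{null}: \text{same sign}\}},$$

so $p \in (0, 1]$ always and results are reproducible given a seed. P-values
are BH-adjusted over the full lncRNA × pathway grid jointly (the conservative
reading of "FDR adjusted"), and the evidence is folded into a single signed
score

$$\mathrm{lncRES} = \begin{cases} 1 - 2p & ES > 0 \\ 2p - 1 & ES < 0, \end{cases}$$

with lncRES $= 0$ for the degenerate $ES = 0$. A (lncRNA, pathway) pair is
significant iff $|\mathrm{lncRES}| > 0.995$ **and** $FDR < 0.05$, both
strict. Note that $|\mathrm{lncRES}| > 0.995$ is equivalent to $p < 0.0025$,
so with 1000 permutations a pair can only pass when at least ~400 null draws
share the observed sign and essentially none of them reaches the observed
magnitude. The nominal permutation p (not the FDR) enters the lncRES formula;
the FDR is a separate condition, matching the two-part filter as published.

## The synthetic world

`simulate_cohort()` emits every input the pipeline needs with planted,
recoverable structure. Expression is a Gaussian latent-factor model: each
feature is a unit-variance linear combination of independent standard-normal
factors plus residual noise, so population correlations are exactly the dot
products of loading vectors and every downstream statistic has a closed-form
oracle. Counts-level realism (negative binomial noise, library size) is
deliberately out of scope: every statistic in the pipeline is
correlation-based and operates on normalized expression.

The default world has 120 samples, 500 genes (10 of them ICP), 300 lncRNAs,
and 5 immune pathways of 40 genes:

* **ICP relatedness.** A shared immune-activity factor on which the 10 ICP
  genes and the 5 related lncRNAs load $\sqrt{0.7}$, giving pairwise
  correlation `rho_signal = 0.7` between every related lncRNA and every ICP
  gene.
* **Planted enrichment.** Each related lncRNA has a private factor carrying
  its non-shared variance, and a "leading edge" of 16 of its pathway's 40
  genes loads $\sqrt{0.8}$ (`rho_pathway`) on that factor, i.e. each core
  gene correlates ≈ 0.49 with its lncRNA after purity adjustment. The
  remaining 24 members are independent noise. The leading-edge design mirrors
  how real enrichments look (a co-regulated core drives ES) and was chosen —
  together with the core size — so that the two properties the generator
  must deliver hold simultaneously: planted pairs saturate the permutation p
  (hence pass $|\mathrm{lncRES}| > 0.995$), and unrelated (lncRNA, pathway)
  pairs rarely fire. A fully co-regulated 40-gene set at loading
  $\sqrt{0.7}$ fails the second property badly (see Limitations).
* **Purity confounding.** Purity is Beta(5, 2), clipped to $[0, 1]$. Twenty
  (lncRNA, gene) pairs load $\sqrt{0.6}$ (`confound_strength`) on the
  standardized purity covariate and on nothing else: their raw Pearson
  correlation is ≈ 0.6 while their purity-adjusted PCC is ≈ 0. The parameter
  is read as the *induced raw correlation* (loading $\sqrt{0.6}$ each)
  rather than a literal loading of 0.6, which would give raw $r \approx
  0.36$ and defeat the purpose of the construction.
* **Interaction list.** All lncRNA × ICP pairs, the ICP–ICP clique, and the
  confounded pairs — so stage 1 tests exactly the pairs a real pipeline
  would, and the confounded pairs demonstrably fool raw Pearson but not the
  purity-adjusted stage.

What a green test on this world does **not** establish: robustness to
count-level noise models, to batch effects, to annotation errors in the
interaction list, or to pathway collections whose sets overlap heavily.

## Numerical choices

* p-values are floored at $10^{-300}$ before any log; $|r| = 1$ yields the
  floor directly rather than 0.
* BH adjustment is implemented in-package (step-up with cumulative minimum,
  capped at 1, NAs passed through) and is verified against a brute-force
  enumeration oracle; `stats::p.adjust` is never the tested path.
* The enrichment score is computed from sorted hit positions in
  $O(k \log k)$; the test oracle is the literal $O(N)$ running sum. On exact
  ties between the positive and negative extremes the positive one wins.
* The permutation stream is a single seeded RNG; library functions restore
  the caller's RNG state on exit.
* `partial_correlation` rejects covariates with $|R| \ge 1 - 10^{-12}$
  against either expression vector (degenerate adjustment).
* The log-rank utility computes the $k$-group chi-square from
  observed-minus-expected sums with the hypergeometric variance, from first
  principles; `survival::survdiff` is used in tests as the oracle only.

## Limitations

* **Gene-label permutation and correlated sets.** When a gene set contains
  internally correlated members, the sampled correlations of *any* vector
  with those members co-move, so the observed ES is more variable than the
  gene-label permutation null admits — a known anti-conservative bias of
  pre-ranked GSEA with label permutation. The acceptance suite measures the
  practical consequence on the default synthetic world (null-pair
  significance stays under 5% there), but users should expect inflated
  significance for tightly co-regulated pathways and treat borderline calls
  accordingly. Sample permutation would fix this but is a different method
  than the one implemented here.
* The lncRES sign convention means a pair with $ES > 0$ but $p > 0.5$ gets a
  (small) negative lncRES; such pairs are never significant, so the quirk is
  cosmetic.
* LASSO/Cox fitting, deconvolution (infiltration scores), ssGSEA signature
  scoring and single-cell analyses are consumed as inputs, not implemented;
  the package evaluates the published risk-score combination and labels
  RECIST responses but does not train models.
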