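---
title: "Methods: from a colony-morphology screen to a weighted interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a colony-morphology screen to a weighted interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonynet)
```

`colonynet` analyses a genome-wide deletion screen of yeast colony
morphology in four connected stages: edge-confidence estimation for a
physical interaction network, overlay of the screen's hit genes, gene-set
association statistics with redundancy grouping, and moderated-t
differential expression for the *flo11*Δ contrast in liquid and solid
media. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

## The edge-confidence model

Interaction databases aggregate evidence of very unequal quality: a
two-hybrid report and a reconstituted-complex experiment do not carry the
same weight. The package models, for each unordered protein pair, the
presence/absence of each experimental technique among the pair's reports,
and combines them with a naïve Bayes classifier:

$$ w_{ij} \;=\; \frac{\pi \prod_t P(t \mid \text{true})}
  {\pi \prod_t P(t\mid\text{true}) + (1-\pi)\prod_t P(t\mid\text{false})} $$

**Assumptions.** Techniques are conditionally independent given the edge's
truth (the naïve assumption), and technique *presence* is informative while
report *multiplicity* is not. Evidence for the same pair is pooled across
sources and each distinct technique enters the product once; repeated
reports of the same technique are frequently correlated (same underlying
experiment re-curated), so counting them once avoids double-counting under
the independence assumption.

**Training sets.** Positives are pairs with at least one literature-curated
low-throughput record. Negatives are pairs whose *most specific
co-annotation* — the smallest GO term shared after annotation propagation —
has at least 1000 annotated genes (`threshold`, default 1000): two genes
whose only functional relationship is membership in an enormous generic
category are very unlikely to interact physically. Pairs sharing no term
are left unclassified rather than called negative, and positive pairs are
excluded from the negative set.

**Smoothing and the prior.** Technique likelihoods use pseudocount
smoothing (`smoothing`, default 0.5, i.e. Jeffreys-style): finite training
sets routinely miss a technique in one class, and a zero likelihood would
veto an edge outright. With `smoothing = 0` a zero count is an error unless
`clamp_zero = TRUE`. The prior defaults to the training-set class balance
and is overridable (`prior`); the trained prior, like every ad-hoc constant,
is echoed into the run manifest so no run hides its configuration.

**Special edge types.** Phosphorylation and dephosphorylation edges carry a
fixed configurable confidence (`phospho_weight`, default 0.8) because their
curated sources do not expose technique evidence in the same form.
Protein–DNA edges use `1 - binding_pvalue` when a binding p-value is
available (clamped into (0, 1]) and a fixed fallback (`pdna_weight`,
default 0.6) otherwise; this monotone, parameter-free transform replaces
the elaborate weighting scheme of dedicated TF-binding pipelines, which is
out of scope here. The network is trimmed at `trim_threshold` (default
0.2): with the default prior and smoothing, edges below this weight are
supported only by techniques that are nearly as frequent among
non-interacting pairs as among interacting ones.

## Screen consensus and hit classes

Each deletion strain is pinned in triplicate and coded as one of
`wild_type_wrinkly`, `smooth`, `semi_smooth`, `extra_wrinkly`, `small`,
`large`. The consensus is the strict majority over the three replicates
(at least 2 of 3); three-way disagreement yields `ambiguous`, which is
reported and excluded from hit classes rather than silently dropped —
replicate disagreement is information about assay noise, not a missing
value. Morphology hits are `smooth ∪ semi_smooth`, size hits
`small ∪ large`; an exclusion list (dubious ORFs, putative proteins) is
subtracted before any enrichment.

With per-replicate penetrance $p$, the probability that the majority call
recovers a planted class is $p^3 + 3p^2(1-p)$ — 0.972 at $p = 0.9$ — which
is the closed form the screen-consensus tests check against.

## Association statistics

A gene set with $K$ members inside the universe, $k$ of them among the $n$
hits, is scored with the cumulative hypergeometric upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated through
`stats::phyper` (log-space, exact); the test suite verifies exact agreement
with exhaustive enumeration of all $\binom{N}{n}$ draws for every feasible
configuration with $N \le 12$.

**The universe matters.** The default background is the set of screened
genes (the deletion collection), not the network nodes: the test's random
model draws "the same number of genes identified in the screen" from what
*could* have been identified. `universe_mode` offers `screened`, `network`
and `annotated` alternatives because the choice changes every $N$ and $K$.
Sets with fewer than 2 in-universe members are not tested (degenerate
tables). Ties in ranked output are always broken by identifier so output is
deterministic.

**ClueGO-style expression enrichment.** For the differential-expression gene
lists the package follows the ClueGO conventions: a two-sided test (double
the smaller tail, cap at 1, direction from which tail is smaller),
Bonferroni correction, terms restricted to ontology levels within
`level_window` (default 3–8, with the namespace root at level 1, so the
window excludes the root and its children) and to terms with coverage
$k/K \ge$ `min_fraction` (default 0.08). Term levels are shortest-path
depths: in a DAG a term can be reached by paths of different lengths and
the shortest one is the level — the suite asserts only root = 1 and
child-of-root = 2 as universal, since alternate paths legitimately invert
parent/child levels.

Redundant enriched terms are grouped by Cohen's kappa on their in-universe
membership indicators, connecting terms with kappa ≥ `kappa_threshold`
(default 0.3) and taking connected components as groups; each group is
represented by its smallest-adjusted-p term (ties by id). Kappa is used
instead of raw overlap because it corrects for the agreement two large
terms would show by chance. When expected agreement is exactly 1 (both
sets empty or both the whole universe) kappa is defined as 1 for identical
sets and 0 otherwise.

## Moderated-t differential expression

The expression stage consumes a normalized log2 matrix with
present/absent detection calls (array preprocessing is out of scope).
Absent calls are masked and a gene needs at least two present replicates
per genotype to be testable in a contrast; untestable genes are flagged,
not dropped silently. Per medium, the *flo11*Δ vs wild-type contrast uses
the empirical-Bayes moderated t: per-gene pooled variances
$s_g^2$ ($d_g$ df) are modelled as $s_0^2 F(d_g, d_0)$, $(d_0, s_0^2)$ are
estimated by moment matching on $\log s_g^2$ (digamma/trigamma moments,
with a Newton inverse-trigamma), and

$$ \tilde s^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t_g = \frac{\widehat{\mathrm{logFC}}_g}{\tilde s \sqrt{1/n_1 + 1/n_2}}
   \sim t_{d_0 + d_g}. $$

The formulas are implemented directly rather than wrapping an external
fitting routine so the stage is self-contained, exact in its limits
($d_0 = 0$ reduces to the classical pooled t; $d_0 \to \infty$ pins every
variance at $s_0^2$), and testable; the suite nevertheless cross-checks
$d_0$, $s_0^2$, $t$ and $p$ against `limma::eBayes` on generated data.
If the moment-matching variance is non-positive (variances essentially
identical), $d_0$ is treated as unbounded and all variances collapse to
$s_0^2$. Genes are selected at corrected $P <$ `alpha` (default 0.05,
BH per contrast) and $|\mathrm{logFC}| >$ `lfc_min` (default 1, i.e.
fold change above 2); the liquid/solid overlay then classifies each gene
as `both_media`, `liquid_only`, `solid_only` or `neither`, with per-medium
up/down states for rendering (core colour = liquid, border = solid).

## Network assembly, complex overlay and condensation

Undirected edges are canonicalized ($i < j$) and duplicates of the same
type merged keeping the pooled-posterior weight; directed types
(phosphorylation, protein–DNA) between the same genes remain distinct
edges. Complexes containing at least one hit are *complemented*: members
that are not hits themselves are added and flagged by deletion viability
(`lethal_member` — essential genes cannot appear in a non-essential
deletion screen — or `reduced_fitness_member`), so a complex is shown
whole even when only part of it is screenable.

For visualization, complexes with ≥ 3 members present in the network
(`condense_min_size`, matching the "more than 2 genes" rendering rule)
collapse into single nodes. A gene belonging to several complexes is
assigned to the complex with the most hits, ties broken by lexicographic
complex id — the membership data say nothing about which copy dominates,
so the rule favours the complex the screen itself implicates, and the
deterministic tie-break keeps output stable. Aggregated inter-node edges
keep the maximum underlying weight ("best evidence" semantics) plus the
underlying edge count; intra-complex edges are counted on the complex
node, so no edge disappears from the bookkeeping and no gene is lost
(conservation is asserted over random networks in the suite).

Exports (SIF with a Cytoscape-style `.eda` weight sidecar, GraphML with
typed attributes, JSON mirroring the node/edge model for web viewers) are
deterministic — sorted nodes and edges, weights rounded to 6 decimals —
and re-import reproduces nodes, edges and weights exactly at that
precision. Edge colour classes follow the standard rendering: green
protein–protein, blue phosphorylation, orange dephosphorylation, red
protein–DNA.

## What the synthetic data do and do not show

The generators produce every input the pipeline consumes, at the study's
scale by default: a 4156-gene universe with planted phenotype modules of
52 smooth, 159 semi-smooth and 268 size-class genes at penetrance 0.9
(1% per-replicate miscalls among wild-type genes); an interactome whose
techniques report true pairs with probability `reliability_pos` and false
pairs with `reliability_neg` (four default techniques with well-separated
likelihood ratios); a rooted GO-like DAG (depth 5, branching 3, a quarter
of terms with a second parent) with a planted ≥ 1000-annotation term so
the negative-pair rule has material at full scale; complexes of 2–12
members occasionally containing essential genes; and a 2-genotype ×
2-media expression design with 3 replicate arrays, gene variances drawn
from a scaled inverse-χ² prior (d₀ = 4, s₀² = 0.04 — the conjugate form
the moderated-t model assumes, making parameter recovery a meaningful
test), ±2 log₂ planted effects, and 5% absent calls.

Passing tests on these data show that the statistics are implemented
correctly and recover planted truth under the model's own assumptions.
They do not show robustness to what real data add: correlated technique
evidence (shared publications), annotation bias (well-studied genes carry
more terms), spatially structured screen artefacts (plate edges), or
expression variance that violates the inverse-χ² prior. The generators are
pure functions of their seed, so every result in the suite and the
acceptance script is exactly reproducible.

## Numerical choices and problem sizes

All tail probabilities are computed in log space via `phyper`/`pt`;
posteriors are combined on the log-odds scale and mapped back with the
logistic, so hundreds of techniques could be multiplied without underflow.
The inverse trigamma uses Newton iteration with the standard asymptotic
fallbacks. Test problem sizes were chosen to make the statistical
assertions sharp while keeping the default suite fast: exhaustive
hypergeometric enumeration to N = 12, null calibration with 2000 resampled
hit sets over 50 complexes, 20-seed recovery runs for planted complexes,
technique ordering and differential expression, and moment-matching
recovery on 2000-gene matrices. The acceptance script runs the full
4156-gene pipeline once and the property measurements at those same sizes.

## Known limitations

* Technique evidence is treated as independent given edge truth; correlated
  assays inflate confident weights.
* The protein–DNA transform `1 - p` is a deliberate simplification of
  dedicated TF-binding weighting schemes.
* Only `is_a` ontology edges are propagated; `part_of` and regulatory
  relations are ignored, which undercounts some terms.
* The two-sided hypergeometric p doubles the smaller tail; other two-sided
  conventions (minimum-likelihood) give slightly different values near the
  mode.
* `run_pipeline()` drives the synthetic study end to end; file-based
  studies use the exported stage functions directly with the `read_*`
  parsers.
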