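---
title: "Methods: cross-tissue consensus biomarker inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue consensus biomarker inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msconsensus)
```

`msconsensus` infers blood-detectable candidate biomarkers of the
relapsing–remitting to secondary-progressive multiple sclerosis (RRMS →
SPMS) transition from several independent case/control expression studies.
This vignette records the statistical model behind each stage, the
parameters that matter, and the design choices that were genuinely open —
together with what the synthetic validation does and does not demonstrate.

## The Rank Product test

For one dataset and one contrast (SPMS vs HC, or RRMS vs HC in blood), let
$x_{gc}$ be the normalized log2 expression of gene $g$ in case sample $c$.
For every case/control sample pair $(c, h)$ we form the per-gene difference
$d_g = x_{gc} - x_{gh}$ and rank genes by it: rank 1 is the most
up-regulated (or, in the opposite orientation, most down-regulated) gene in
that pair, with ties averaged. The statistic is the geometric mean rank
across the $K$ pairs,

$$\mathrm{RP}_g = \Big(\prod_{i=1}^{K} r_{g,i}\Big)^{1/K},$$

computed in log space. Being rank-based, it is invariant under increasing
affine transforms of the expression values and robust to the heavy tails of
microarray intensities. All $n_\text{case} \times n_\text{control}$ pairs
are used, capped at `max_pairs = 400` by a seeded uniform subsample (at the
default arm sizes the cap is never hit).

Significance comes from a label-permutation null pooled across genes: each
of $B$ permutations (default 200) redraws the case set uniformly from the
pooled samples, and the empirical tail is

$$p_g = \frac{1 + \#\{(b, g') : \mathrm{RP}^{*}_{g'b} \le \mathrm{RP}_g\}}
{1 + B \cdot G}.$$

The plus-one correction keeps p-values strictly positive (floor
$1/(1+BG)$). Benjamini–Hochberg adjustment of the pooled p-values is
algebraically identical to the "percentage of false prediction" this class
of methods traditionally reports: $q_g = \#\{rp^* \le rp_g\} / (B \cdot
\mathrm{rank}_g)$. A gene is a DEG when $q < \alpha$ (default 0.05) in
either orientation, with **no fold-change filter**; the reported `log2fc`
(mean case − mean control) carries the authoritative direction. A gene
significant in both orientations takes the smaller q; at an exact tie it is
called `up` — a deterministic rule chosen because the downstream selection
focuses on up-regulation.

Two numerical points. First, rank products of *different* rank multisets
can be exactly equal ($2 \cdot 3 = 1 \cdot 6$), so the tail count treats
values equal up to a $10^{-9}$ relative tolerance as ties; otherwise the
count would depend on floating-point summation order. Second, with ≤
$\binom{8}{4}$ relabelings the permutation null can be enumerated
exhaustively (`exhaustive = TRUE`), which the test suite compares against
an independent brute-force oracle.

A property worth knowing: because the null is pooled across *all* genes,
genes with real effects contaminate it — under an imbalanced relabeling a
truly shifted gene still attains an extreme rank product. With many
same-direction DEGs this makes the test conservative (the planted-truth
simulations below quantify the consequence). This is inherent to the
pooled-null construction, not an implementation artifact; our
implementation in fact outperforms a per-gene Welch t-test with BH in the
simulated regime.

## Preprocessing

Raw intensities are mapped by $\log_2(x+1)$ (zero intensities allowed,
negative ones are a named data error), then quantile-normalized so every
sample shares the empirical distribution of across-sample order-statistic
means; tied values receive the mean of the reference values at the tied
positions, making the operation deterministic and idempotent (tolerance
$10^{-10}$). The heavy lifting is `limma::normalizeQuantiles(ties =
TRUE)`, whose tie convention matches this contract. Probe-to-gene collapse
averages probe rows per gene by default (`median` and `max-mean-probe` are
available); real platforms resolve probes by curation, which cannot be
automated, so the strategy is explicit and configurable. Background
subtraction is a deliberate no-op for synthetic data, which is generated
background-free.

## The consensus filter

A gene passes when (a) it is a DEG in at least `brain_min_fraction = 0.5`
of the brain datasets measuring it, with an unambiguous modal direction (a
50/50 split is `mixed` and fails — an inconsistent biomarker is unusable),
and (b) it is a DEG with that same direction in at least
`blood_min_fraction = 0.75` of the blood datasets measuring it. Genes
absent from a dataset's platform are excluded from that dataset's
denominator, since heterogeneous arrays measure different universes.

The 75% blood rule admits two readings. The default (`strict`) counts only
datasets that call the gene significant in the modal direction — matching
the requirement that consensus genes be *identified as DEGs* in blood. The
`lenient` alternative treats non-significant blood datasets as
non-contradictory (at least one blood dataset must still call the gene),
for users who read "consistent" as "not inconsistent". Both are
implemented; neither reading is asserted as the historically correct one.
The up/up refinement (`derive_rulu()`) keeps genes up-regulated in both
tissues — up-regulation is the practical direction for a blood assay.

## Network subcluster and enrichment

The interaction stage induces the RuLu genes on a weighted gene–gene graph,
keeps edges at confidence ≥ `confidence_min = 0.4` (the conventional
medium-confidence cutoff of interaction databases), and returns the largest
connected component. "Subcluster" is operationalized as a connected
component rather than a modularity/MCL cluster: the upstream analyses this
mirrors present one highlighted connected subnetwork, and a component is
deterministic. Ties in size break toward the lexicographically smallest
member set; singletons are never reported as a cluster.

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for an overlap of $k$ of the $K$ term genes in a query of $n$
from a universe of $N$, via `stats::phyper`. BH runs within each namespace
(BP/CC/MF) separately, because the three ontologies are reported as
separate families. Terms with zero overlap are omitted — they carry no
evidence and would inflate the BH family size. The default universe is the
set of genes measured in at least one dataset intersected with the library
genes; an explicit universe can be supplied. Terms whose overlapping genes
share a Jaccard index ≥ `fuse_jaccard = 0.5` merge transitively into fused
nodes labeled by the most significant member — collapsing the
near-duplicate terms that ontology libraries are full of.

## RRMS specificity and the three layers

The blood-only RRMS-vs-HC contrast goes through the same DEA and the same
75% consistency rule. Each target gene is then `same` (RRMS direction
equals the SPMS direction), `opposite` (reversed), or `specific` (no RRMS
call); the three categories partition the target set exactly, and genes
missing from the RRMS platforms are `specific` by definition (logged).
Candidates are `specific ∪ opposite` — everything whose behavior differs
from RRMS, the two granularities being reported separately as well.

The layered comparison runs paired enrichments at three granularities:
CLUp (strictly `specific` vs `same`), RuLu (the same contrast), and all
consensus DEGs (`specific ∪ opposite` vs `same` — at this layer the
question is *different* behavior, not strict specificity). A layer's
difference is the set of BP terms enriched on the differing side and not
on the shared side. The final set combines layers by strict intersection
(default), the most conservative reading; `union` and `per-layer` modes
are provided because the combination rule is not externally fixed. A layer
with an empty differing side is skipped (it carries no information); an
empty shared side contributes no exclusions.

## The synthetic study generator

The generator emulates the structure of a six-study cross-tissue corpus:
two brain datasets (SPMS vs HC) and four blood datasets (SPMS, RRMS, HC),
ten samples per arm by default — a deliberately scaled-down version of the
real corpus (which has tens of samples per arm and ~20k genes) sized so
permutation tests stay desk-scale. Expression is log2-normal: one baseline
per gene from Uniform(4, 12) shared across datasets, a per-dataset additive
batch shift of $\log_2(\text{batch scale})$ (so quantile normalization has
real work to do), independent Gaussian noise, and planted per-class arm
shifts of ±1.5 log2 units. RRMS arms appear only in blood, as in the real
corpus. Five classes partition the genes: `null`,
`spms_up_specific`/`spms_down_specific` (SPMS arm only), `shared_up` (both
disease arms up) and `opposite` (up in SPMS, down in RRMS) — exactly the
categories the specificity stage must separate.

Defaults worth justifying:

* **Class mix** (20 up-specific, 5 down-specific, 5 shared-up, 3 opposite
  in 200 genes, ~16% DE): the rank-based statistic saturates when too many
  genes shift in the same direction — they compete for the same top ranks,
  and real effects contaminate the pooled permutation null. The default
  keeps the generator inside the regime where a rank statistic is a
  reasonable tool, which is also the regime the method's own validation
  example fixes (20 planted up-specific genes in a 200-gene universe).
* **Noise SD 0.5** on the log2 scale: typical residual spread of expressed
  microarray genes after normalization (0.2–0.7). The planted 2.8-fold
  effect is then a 3-SD effect — the kind of change a 10-per-arm microarray
  study is actually powered to find. At 1.0 (a 1.5-SD effect) *no*
  per-gene test recovers the planted genes reliably at these arm sizes
  (an oracle t-test reaches ~23% per-dataset sensitivity), so simulations
  at that noise level measure the design's futility, not the pipeline's
  correctness.
* **Interaction graph**: the SPMS-up-specific genes form a
  high-confidence clique (weights Uniform(0.7, 1)) over an Erdős–Rényi
  background (probability 0.01, weights Uniform(0, 1)), so subcluster
  extraction has a planted answer.
* **Gene sets**: `enriched_sets = 3` terms are seeded with 80%
  SPMS-up-specific genes (known ORA positives); the rest are uniform draws,
  namespaces cycling BP/CC/MF.

What the generator does **not** emulate: probe-level chemistry, real GO DAG
topology and term nesting, correlated gene–gene expression (noise is
independent across genes), dataset-specific variance profiles, and
confounders such as age, sex or treatment. Passing tests therefore show the
*procedure* is implemented correctly and recovers planted structure under
honest noise — not that the thresholds are optimal for any real corpus.

## Determinism and problem sizes

One global seed fans out via a fixed splitting rule (`derive_seeds()`: a
seeded draw of one integer per stage) to the simulation, library, graph,
and each dataset's DEA, so a full run is byte-reproducible and any stage
can be re-run standalone with the stream it saw inside the pipeline.
Manifests round-trip losslessly through JSON and carry a schema version
that is checked on read.

The shipped validation operates at the generator's default scale: 200
genes, six datasets, 200 permutations, ten samples per arm; Monte-Carlo
properties (type-I control, planted-gene recovery, null ORA calibration)
average 10–20 replicate seeds, and brute-force oracles (exhaustive
relabeling, combinatorial hypergeometric sums, step-up BH, union-find
components) cover the small-design regime where enumeration is feasible.
A full pipeline run at this scale takes a few seconds.

## Known limitations

* The pooled permutation null is conservative when many same-direction
  effects are present (see above); sensitivity claims are tied to the
  planted DE fraction.
* The consensus filter is set-based, as the inference chain it implements:
  it does not pool effect sizes across datasets, and a gene measured in
  only one blood dataset faces a weaker requirement than one measured in
  four.
* Paired designs, covariate adjustment and moderated-variance statistics
  are out of scope; the DEA is strictly two-sample.
* ORA treats terms as flat sets — no DAG-aware propagation or
  redundancy reduction beyond Jaccard fusion.
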