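---
title: "Hierarchical cross-entropy over a cell-ontology DAG: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cross-entropy over a cell-ontology DAG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hceloss)
```

## The model

Cell-type labels live on a DAG: nodes are ontology terms, and a directed
edge `child -> parent` states that the child is a subtype (`is_a`) of the
parent. Multiple parents are permitted — real cell-ontology terms have
them — so descendant sets are always computed through reachability, never
by counting tree paths.

A classifier outputs raw probabilities $\mathbf{p} = (p_1,\dots,p_C)$ over
the $C$ ontology classes (a softmax over the model's logits; the softmax
is the conventional map for the architectures involved). The flat weighted
cross-entropy for a sample with true class $t$ is
$\mathcal{L}_\mathrm{CE} = -w_t \log(p_t + \epsilon)$. The hierarchical
cross-entropy replaces $p_t$ by the *adjusted score*

$$s_i = p_i + \sum_{j \in \mathcal{D}(i)} p_j, \qquad \mathbf{s} = R\,\mathbf{p},$$

where $\mathcal{D}(i)$ is the descendant set of class $i$ and $R$ is the
reachability matrix: $R_{ij} = 1$ iff $j$ is $i$ or a descendant of $i$.
$R$ is the transitive closure of the inverted `is_a` adjacency with the
diagonal forced to one; it is reflexive, antisymmetric and transitive (a
partial order), and every constructed $R$ is checked against those
properties in the test suite. Because each descendant contributes exactly
one entry of $R$, multi-parent terms are never double-counted. The loss is

$$\mathcal{L}_\mathrm{HCE} = -w_t \log(s_t + \epsilon),
\qquad w_i = \frac{N}{C\,n_i}, \qquad \epsilon = 10^{-6}.$$

Two consequences drive everything else. First, $s_t \ge p_t$, so
$\mathcal{L}_\mathrm{HCE} \le \mathcal{L}_\mathrm{CE}$ pointwise, with
equality on an edge-free ontology — flat classification is the special
case $R = I$. Second, probability placed on any subtype of the annotated
class is not penalised, which matches the evaluation convention for
mixed-granularity annotations: a predicted label is correct iff it equals
the ground truth or is a descendant of it; a coarser (ancestor) prediction
is wrong.

### Evaluation

Per-class true/false positives and false negatives are tallied after
remapping every hierarchically correct prediction to its ground-truth
class. Remapping is our bookkeeping choice: the correctness rule is
defined per cell, and remapping is the one rule that makes the per-class
counts consistent with it (a subtype prediction becomes a true positive of
the annotated class rather than a false positive of the subtype). Macro F1
is the unweighted mean of per-class F1 over the classes *present in the
evaluation set's ground truth* (an `include` argument exposes the
all-classes alternative); the degenerate 0/0 F1 is defined as 0 so that
absent, never-predicted classes cannot inflate the average. Arms are
compared per class with a two-sided paired t-test across matched seeds and
Holm–Bonferroni adjustment at $\alpha = 0.05$; classes whose difference
vector has zero variance have no defined t statistic and are flagged
untestable and excluded from the adjustment family.

## Tunable parameters

* `epsilon` (default $10^{-6}$, dimensionless): added *after* aggregation,
  i.e. $\log(s + \epsilon)$, and reused identically in the CE loss so the
  two losses are exactly comparable. Note $-\log(1+\epsilon) < 0$: a
  perfectly confident correct prediction has a loss of $-10^{-6}$, not 0.
* class weights: $w_i = N/(C n_i)$ from the *training split only*. A class
  absent from training ($n_i = 0$) gets weight 0 and a warning — the
  alternative, $N/0$, is undefined, and an unlearnable class should not
  dominate the objective. Samples of weight-0 classes contribute zero
  loss.
* batch reduction: weighted mean, $\sum_b w_{t_b} \ell_b / \sum_b w_{t_b}$,
  the usual weighted-NLL convention.
* training (`train_config()`): plain SGD with momentum 0.9, learning rate
  0.01, batch size 64, 80 epochs by default. The rate was chosen once for
  stability on size-factor-normalized log counts, whose entries span
  roughly 0–8; rates an order of magnitude larger diverge on such inputs.
  Optional early stopping on validation macro F1 is off by default.
* inference: argmax of the *raw* probabilities, ties to the lowest class
  index. Whether inference should instead argmax the adjusted scores is
  genuinely open (the hierarchy is described inside the loss, and the
  evaluation framework scores raw predictions); both are exposed
  (`adjusted = TRUE`), raw is the default.

## Ontology handling

Node order is fixed lexicographically at load time so index $i$ means the
same class in every matrix, vector and checkpoint; checkpoints store the
node ordering and evaluation refuses a mismatch rather than silently
misaligning classes. OBO ingestion is deliberately minimal: `[Term]`
stanzas with `id`, `name`, `is_a`; all other stanzas and relation types
(e.g. `part_of`) are ignored with a warning, because only `is_a` defines
the label hierarchy. Cyclic input is rejected with the offending cycle
listed.

Pruning an ontology to an observed label set keeps exactly the observed
nodes and connects `u -> v` iff `v` is an ancestor of `u` in the full
graph with no observed node strictly between them — the transitive
reduction of the induced ancestry partial order. Nothing downstream
consumes more than ancestry (the loss and the evaluator both work off
reachability), so the reduction loses nothing while keeping the graph
minimal; this is our choice where no single convention exists, and it is
property-tested: ancestry among observed nodes is preserved exactly.

## What the synthetic generator emulates

`sim_config()` defaults define the package's reference conditions: a
rooted ontology with 8 leaves, depth ≤ 3, and a 10% chance per internal
node of a second parent; 60 genes of which each leaf elevates 5 markers
8-fold; negative-binomial counts (size 2) with an expected library size of
2,000; 4 studies of 300 cells (3 donors each); a gene-wise log-normal
study effect with sd 0.8; and label coarsening probability
`granularity_gamma = 0.4` — each affected cell's leaf label is replaced by
a uniformly chosen strict ancestor, emulating studies that annotate at
different depths. The study-effect sd was set so that classifiers show a
clear in-distribution → out-of-distribution macro-F1 drop, the
generalization failure the loss is meant to mitigate; with a much weaker
effect the held-out study is statistically indistinguishable from the
training studies and the OOD question dissolves.

The generator reproduces the *structure* of the problem, not the scale or
texture of a real atlas: counts are 60-dimensional rather than ~19k
protein-coding genes, there are no doublets, no ambient RNA, no
platform-specific dropout, donor effects default to zero, and leaves are
equiprobable rather than heavily imbalanced. A passing benchmark therefore
demonstrates that the loss behaves as designed when annotation granularity
is mixed and studies shift — not that any particular macro F1 would be
attained on real data.

The benchmark (`run_ood_benchmark()`) fixes one ontology, then per seed
re-draws counts, coarsening and weight initialisation, trains paired CE
and HCE models (the loss is the only difference), and evaluates
descendant-aware macro F1 on a donor-partitioned ID split and a
held-out-study OOD split. Problem sizes — 1,200 cells, 12–13 classes,
10 seeds, 80 epochs — were chosen so the whole comparison runs in well
under a minute per architecture on one CPU while leaving the paired test
adequately powered. Two structural sanity properties anchor it: with
`granularity_gamma = 0` every label is a leaf, the two losses are
*identical* functions, and the CE/HCE gap is exactly zero at matched
seeds; and on an edge-free ontology the full training trajectories
coincide.

## Numerical and degenerate-case choices

* Acyclicity is verified at construction; self-loops and dangling edge
  endpoints are rejected by name.
* `adjust_scores` validates dimensions; probability inputs are checked to
  be nonnegative and sum to 1 within $10^{-6}$.
* Gradients of the batched loss through the softmax are analytic and are
  verified against central finite differences at tolerance $10^{-5}$.
* All-zero cells cannot be size-factor normalized and are rejected listing
  the offending cell ids; all-zero genes pass through as zeros.
* Ties in argmax inference resolve to the lowest class index,
  deterministically.
* Every stochastic component (ontology growth, counts, coarsening, batch
  order, initialisation) is governed by explicit seeds; generators are
  bitwise reproducible given seed and config, and the RNG state of the
  caller is restored afterwards.

## Known limitations

* The training loop is plain SGD on dense matrices; it is meant for
  desk-scale experiments and method development, not for atlas-scale
  corpora or GPU training.
* Transformer-style tabular architectures are out of scope; the linear
  classifier and MLP isolate the effect of the loss, which is
  architecture-agnostic by construction.
* OBO support covers the `is_a` subset only; richer ontology semantics
  (cross-products, obsolescence, versioned releases) are not reconciled.
* The hierarchical remapping convention makes per-class precision of
  internal nodes optimistic by design: correct subtype predictions count
  toward the annotated class. This is intentional and matches the
  correctness rule, but it means per-class numbers are not comparable to a
  flat confusion matrix.
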