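---
title: "Simulating cross-silo federated learning for variant pathogenicity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cross-silo federated learning for variant pathogenicity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Supervised pathogenicity scores for human genetic variants are usually trained
on centralized curated repositories, while most clinically labeled variants sit
in institutional collections that privacy law keeps off-limits. Cross-silo
horizontal federated learning (FL) offers a way out: a handful of institutions
("silos", "clients") share one feature space and train a common model by
exchanging only parameters with a coordinating server. `fedvariant` is an
in-process simulation of that setting for binary pathogenic-vs-benign
classification, covering the full experimental battery one needs to judge
whether FL is worth adopting: federated vs pooled (CDS) vs single-silo
baselines, collaborative cross-validation, client dropouts, and a
random-repartition null that asks whether the silo structure carries non-IID
signal.

Everything runs in one R process. "Clients" are plain data holders; the server
object only ever receives parameter vectors and sample counts, so the
simulation respects the information-flow constraints of real FL even though no
networking is involved.

## The federated round

One round: the server broadcasts the global parameter vector; a random subset
of clients (fraction `client_rate`, at least one, round-half-up) each run 10
local epochs of mini-batch gradient descent; the server combines the returned
vectors. Two aggregation families are implemented:

* **FedAvg / FedProx** — dataset-size-weighted averaging over the round's
  participants, \(w \leftarrow \sum_i (n_i/\sum_j n_j)\, w_i\). FedProx adds
  \((\mu/2)\lVert w - w_{\text{global}}\rVert^2\) to each client's local loss;
  with \(\mu = 0\) under SGD it *is* FedAvg, and the package treats that as an
  exact identity (tested to machine precision).
* **FedAdagrad / FedAdam / FedYogi** — the weighted-average client delta
  \(\Delta\) is treated as a pseudo-gradient and pushed through a server-side
  adaptive step \(w \leftarrow w + \eta\, m /(\sqrt{v} + \tau)\), with
  \(m, v\) updated per algorithm (Adagrad: \(m=\Delta\), \(v \mathrel{+}=
  \Delta^2\); Adam: exponential moments with \(\beta_1 = 0.9,
  \beta_2 = 0.999\); Yogi: \(v \leftarrow v - (1-\beta_2)\Delta^2\,
  \mathrm{sign}(v - \Delta^2)\)). \(v\) is initialised to \(\tau^2\). These
  recursions are checked against hand-unrolled scalar oracles in the tests.

Averaging weights are renormalised over the *sampled* clients of the round.
When a round's subset is partial, unsampled clients simply keep waiting — the
cross-silo assumption is that clients are always available, so no straggler or
failure model is simulated.

Centralized (CDS) training deliberately uses the same schedule as a federated
client — segments of 10 epochs with a fresh optimiser state per segment, one
early-stopping evaluation per segment — so that CDS and FL differ only in data
locality and aggregation. A corollary used as a test oracle: FedAvg with a
single full-participation client is *bit-identical* to the centralized loop
under a shared seed, which exercises the whole client/server machinery against
an independent plain training loop.

## Models

Both classifiers are differentiable, trained by hand-written backpropagation
on binary cross-entropy (negative log-likelihood for the forest), with SGD
(momentum 0.9) or Adam, weight decay \(10^{-4}\), and all trainable state
exposed as one flat parameter vector — the unit of federated exchange.

**MLP.** "Three-layer" counts input and output: input → one hidden layer
(3–9 rectified units in the study grid) → sigmoid output. Batch normalization
on the hidden pre-activations is optional; its running statistics are part of
the model state, and the federation exposes both policies for them:
`aggregate` (averaged like any coordinate) and `keep_local` (excluded from
exchange, persisting per client).

**Shallow neural decision forest (sNDF).** A fully connected layer produces
one activation \(f_n(x)\) per split node of each tree; the routing probability
is \(d_n(x) = \sigma(f_n(x))\), a leaf's reach probability is the product of
routing probabilities along its root-to-leaf path, the tree predicts the
reach-weighted mixture of leaf class distributions \(\pi_l\), and the forest
averages its trees. Design choices worth stating:

* Leaf distributions are parameterised as unconstrained logits mapped through
  a row-wise softmax and trained jointly by gradient, rather than by the
  alternating convex update of the original formulation. Joint training keeps
  every parameter in the one flat vector that federated averaging requires; an
  alternating update has no well-defined federated counterpart.
* Per-tree feature subsetting (`feature_rate`) is a fixed Bernoulli mask drawn
  once per tree at initialisation (redrawn if a tree would lose all features).
  Masked weights are zero at initialisation and their gradients are zeroed, so
  they stay zero through training *and* aggregation. Finite-difference
  gradient checks therefore exclude mask-frozen coordinates: perturbing them
  steps outside the model family on purpose.
* Reach probabilities telescope to 1 per tree by construction; the test suite
  asserts this to \(10^{-9}\) and checks analytic gradients against central
  finite differences to a relative \(10^{-4}\).

## Feature encodings

SNVs are encoded in 60 dimensions: 25 one-hot values for the five-nucleotide
window centred on the mutated position (position-major, alphabet A, C, G, T,
N), then seven phyloP conservation tracks (100, 470, 3, 4, 7, 17, 20 species)
over the five positions. CNV deletions are encoded in 38 dimensions: a
22-column gene block summarising the overlapping-gene table (maximum across
genes for quantitative features, *except* minimum expression and the shortest
network paths to haploinsufficient/triplosensitive genes, which take the
minimum; presence-of-at-least-one-gene for categorical features; plus the
overlapping-gene count) followed by 16 region features (six regulatory
coverage fractions, max recombination/CADD/GERP, max gene density, four
overlap flags, distances to centromere and closest telomere).

The flat 38-column order is not fully pinned down by the published feature
groups, so the package freezes one canonical manifest
(`cnv_feature_names()`), writes it as JSON next to every encoded matrix, and
treats it as immutable. Two conventions in it are the package's own: the six
protein-network features are degree, PageRank, betweenness, closeness and the
two shortest paths (the published list names four of six; two standard
centralities fill the count), and the overlapping-gene count is included as a
gene-block column. When a CNV overlaps no gene, quantitative max-rule
features take 0, minimum expression takes 0, and shortest paths take a
documented cap of 100 (an effectively infinite network distance); flags are 0.

Feature standardisation (z-scoring fit on the training silos only, applied to
every split) is a pipeline option, default on for both models: gradient
training on mixed-scale features demands it, and fitting the scaler on
training data only keeps the test pools honest.

## The synthetic cohort generator

Real submitter-attributed collections are emulated, not downloaded. A cohort
has: silos with configurable (typically heavily skewed) sizes; a temporal
split — training records dated in the year before `split_date`, one test pool
dated after it; a second test pool contributed by silos that did not
participate in training (made disjoint by construction, since only
"non-participating sites" is specified); 1:1 class balance by random
downsampling of each silo's majority class; and for deletion CNVs, benign
records paired to pathogenic ones by greedy nearest-neighbour matching on log
genomic length (descending pathogenic length), with the pathogenic record's
submission date copied to its match — dates are synthetic, so the
same-submission-date constraint is emulated by copying.

Payloads come from class-conditional Gaussians with shared unit diagonal
covariance. `class_sep` is the mean separation *per informative dimension*
(the centre position of each conservation track for SNVs), in s.d. units; the
default of 3 gives a cleanly separable cohort (Bayes AUC ≈ 1), the canonical
condition for the recovery experiments. Per-silo mean shifts create non-IID
silos; `shift_mode = "pathogenic"` applies a silo's shift to its pathogenic
class only, emulating collections whose pathogenic variants cluster by client
of origin — the structure that distinguishes CNV-like from SNV-like
collaborations. Whole-silo shifts (both classes equally) turn out to degrade
federated training only mildly, because every client still sees the same
class *contrast*; the class-conditional mode is what reproduces the
non-IID signature in the null experiment below. Chromosomes (1–22, X; no Y,
matching the 23-classifier leave-one-chromosome-out design) are drawn
uniformly unless weighted, with all 23 symbols guaranteed present when the
cohort is large enough. Report dates are uniform within their windows — only
the before/after relation matters to the splits.

What the generator does *not* emulate: real annotation resources (conservation
from alignments, constraint scores, regulatory builds — inputs arrive as
tables), linkage between chromosome and features, label noise, and
inter-feature correlation beyond the class means. Passing tests therefore
demonstrate that the machinery is correct and that the statistical designs
behave as intended under a known generative model — not that any particular
AUC level would be attained on real cohorts.

## Evaluation battery

* **AUC-ROC** is the rank (Mann–Whitney U) form with half-credit ties,
  verified against brute-force pairwise concordance on random instances.
* **Leave-one-chromosome-out**: 23 folds, one per symbol; a record is scored
  only by the model that never saw its chromosome. Folds with no held-out
  records are retained and flagged; an empty training side is a flagged error.
* **Collaborative cross-validation**: each silo splits locally into k = 10
  near-equal folds; global fold f is the union of the silos' folds f. The same
  plan object is reused across compared methods, so FL and CDS consume
  byte-identical splits.
* **Early stopping**: stop after 20 evaluations without strict improvement,
  return the best round. The published rule counts 20 epochs; for federated
  runs the server's unit of progress is the round, so patience is 20 rounds.
* **Dropout study**: all-clients plus one-excluded-at-a-time (K+1 conditions)
  in both modes; the all-clients condition is bit-identical to a standalone
  run under the same seed.
* **IID-partition null**: training records are randomly reassigned to the same
  silo ids with sizes preserved; the original assignment's median AUC over
  seeds is placed against the null distribution of partition medians via a
  z-score (a normal approximation, kept as such and documented), alongside
  quartiles and 1.5 IQR bounds. The study's 100 partitions × 30 seeds are
  defaults; desk-scale runs use 20 × 3.
* **Model comparisons** use the median across seeds (not the mean) and
  two-sided Wilcoxon rank-sum tests on per-seed AUCs, without multiplicity
  correction.
* **Grid enumeration** reproduces the study's 1344 federated settings:
  per model, FedProx contributes 4 learning rates × 2 optimizers × 2 client
  rates × 6 μ = 96, and each adaptive algorithm 4 × 2 × 2 × 4 server rates ×
  3 τ = 192; (96 + 3·192) × 2 models = 1344.

## Numerical and scale choices

Seeds: one root seed drives everything through a mixing function
(`derive_seed`), so cohorts, client sampling, batch schedules and
initialisations are reproducible bit-for-bit; derived seeds stay below
\(2^{31}\). Client-count rounding is round-half-up with a floor of one.
Batch-norm uses biased batch variance, momentum 0.1 and \(\epsilon = 10^{-5}\);
scores are clipped away from 0/1 by \(10^{-12}\) inside the loss only.
Constant features scale to zero rather than NaN. The proximal term behaves as
an attractor only inside fixed-step SGD's stability region (\(\mu\,\eta\)
well below 1); the tests demonstrate monotone shrinkage toward the anchor
across μ decades within that region rather than at astronomically large μ,
where fixed-step gradient descent itself diverges.

Problem sizes in the tests and acceptance runs are the package's desk-scale
choices: recovery uses a 2-silo cohort of 2000 variants (8 rounds of 10 local
epochs); the null calibration uses four silos totalling 320 variants, 20
partitions × 3 seeds, repeated 10 times; the workflow scripts use a few
thousand variants. At these sizes every experiment reruns from scratch in
minutes on one CPU.

## Known limitations

In-process simulation only: no transport, stragglers, asynchrony, secure
aggregation, or privacy mechanisms (homomorphic encryption, differential
privacy) — those are deployment concerns outside this package's question. The
null experiment's z-score leans on a normal approximation with few null
draws. The sNDF is the shallow variant (no convolutional feature extractor),
binary outputs only despite multiclass-capable leaf distributions, and the
non-differentiable baselines (random forest, XGBoost) are deliberately out of
scope since they have no federated counterpart here.
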