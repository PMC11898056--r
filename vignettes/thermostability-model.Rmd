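---
title: "Modeling protein thermostability from sequence embeddings and contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein thermostability from sequence embeddings and contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabnet)
```

## The problem

A protein's thermostability — summarized either as an organism-level
category (Cryophilic, −20–5 °C; Psychrophilic, 5–25 °C; Mesophilic,
25–45 °C; Thermophilic, 45–75 °C; Hyperthermophilic, above 75 °C), a binary
hot/cold split at 45 °C, or a melting temperature $T_m$ in °C — is shaped
jointly by its sequence and its three-dimensional structure. Protein
language models (PLMs) provide two complementary views of a protein of $L$
residues without any experimental structure: a per-residue embedding matrix
$\mathbf{P} \in \mathbb{R}^{L \times F}$ and a residue–residue contact map
$\mathbf{A} \in [0,1]^{L \times L}$ whose entry $a_{nm}$ scores the
interaction strength between residues $n$ and $m$. `stabnet` consumes both
and predicts the thermostability target. It deliberately does **not** run a
PLM itself: embeddings and contact maps are inputs, which keeps the package
lightweight and the model testable against synthetic data with a known
generating process.

## The model

**Sequence branch.** A per-residue MLP lifts the pretrained features to a
learned representation
$\mathbf{X} = \sigma(\cdots\sigma(\mathbf{P}W^{(0)} + b^{(0)})\cdots)
\in \mathbb{R}^{L\times D}$, with ReLU activations. Each row depends only on
its own residue. Depth is 2 ($F \to D \to D$) by default; the depth is a
free architectural choice and configurable.

**Structure branch.** A graph convolutional network propagates the sequence
representation over the contact graph. With self-loops
$\tilde{\mathbf{A}} = \mathbf{A} + \mathbf{I}_L$, degrees
$D_{ii} = \sum_j \tilde{A}_{ij} + c$, and
$\hat{\mathbf{A}} = \mathbf{D}^{-1/2}\tilde{\mathbf{A}}\mathbf{D}^{-1/2}$,
each of the (default 2) layers computes
$\mathbf{H}^{(l+1)} = \sigma(\hat{\mathbf{A}}\mathbf{H}^{(l)}W^{(l)})$,
starting at $\mathbf{H}^{(0)} = \mathbf{X}$ and ending in the structure
representation $\mathbf{G}$. Contact weights are used as-is (no
binarization): the PLM's contact probabilities already encode interaction
strength. The constant $c$ (default $10^{-6}$) guards against empty rows;
with self-loops every row sum is at least 1, so it is a pure safeguard, and
self-loops are added even when an input already has a nonzero diagonal.
Classic GCN layers carry no bias; a configurable `gcn_bias` flag adds one.

**Residue-type-guided contrastive enhancement.** During training, each
protein contributes a triplet-style contrastive term that ties the two
branches together. $L_s$ residues are sampled uniformly without replacement
(all of them for short proteins); their rows of $\mathbf{X}$ are the
*anchors* $\mathbf{X}_s$, the same residues' rows of $\mathbf{G}$ the
*positives* $\mathbf{G}_s$. For each anchor, $K$ *negatives* are drawn from
the sampled residues whose amino-acid type differs (with replacement only
when fewer than $K$ candidates exist). Similarity is an $\omega$-scaled
cosine, $\Psi_{ij} = \omega\cos(x_i, g_j)$ with $0 < \omega < 1$, and the
identity mask selects same-index pairs:

$$
\mathcal{L}_{pos} = -\frac{1}{L_s}\sum_i \log\sigma(\Psi_{ii}), \qquad
\mathcal{L}_{neg} = -\frac{1}{M}\sum_{i,k} \log\sigma\!\big(-\omega\cos(x_i, x_{n(i,k)})\big),
$$

with $\sigma$ the logistic function and $M$ the number of anchor–negative
pairs; $\mathcal{L}_{cont} = \mathcal{L}_{pos} + \mathcal{L}_{neg}$. The
positive term is strictly decreasing in every diagonal similarity and the
negative term strictly increasing in every anchor–negative cosine, so
minimizing the sum pulls each residue's sequence and structure views
together while pushing apart residues of different types. The "categories"
guiding the scheme are the 20 canonical amino-acid types; residues of
unknown type (wildcards) are excluded both as anchors and as negatives. A
fresh sample is drawn at every forward pass, seeded from the run seed;
at evaluation time the term plays no role.

The functional form deserves a note: the published account of this loss
family fixes the triplet structure (anchor $\mathbf{X}_s$, positive
$\mathbf{G}_s$, type-mismatched negatives from $\mathbf{X}_s$), the
identity-mask diagonal selection, and the $0<\omega<1$ scale, but leaves
room in the similarity kernel. We implement the $\omega$-scaled cosine with
logistic log-losses as the realization satisfying every stated property,
and expose a `kernel = "dot"` alternative; the choice is documented rather
than hidden because it is the one place the architecture is
reconstruction-by-contract rather than forced.

**Aggregation and heads.** Proteins vary in length, so each branch is
pooled by grouped self-attention:
$\mathbf{A}_g = \mathrm{softmax}(W_2\tanh(W_1\mathbf{H}^{\top}))
\in \mathbb{R}^{D''\times L}$ with the softmax along the residue axis,
$\tilde{\mathbf{G}} = \mathbf{A}_g\mathbf{H}$, and the protein vector is
the mean of the $D''$ group rows. Each group can attend to a different
stability-relevant neighborhood. The two pooled vectors are concatenated
and a single fully connected layer produces class logits or
$\hat{T}_m$ in °C. The total loss is
$\mathcal{L} = \mathcal{L}_{pred} + \alpha\,\mathcal{L}_{cont}$, with
cross-entropy for classification and RMSE for regression; $\alpha = 0$
ablates the contrastive term.

Two realization choices were genuinely open. First, the attention map is
$W_2\tanh(W_1\mathbf{H}^\top)$ with $D_a = D$ hidden units and $D'' = 4$
groups: the mechanism's two learnable parameters are fixed by the design
but their dimensions and nonlinearity are not, and the tanh/softmax pair is
the standard self-attentive pooling construction. Second, "the same
self-attention pooling" for both branches is read as the same *mechanism*
with independent weights per branch (a `share_attention` flag ties them):
sequence and structure representations live in different spaces, and
sharing would couple their geometries for no stated reason.

## Optimization

Training uses Adam (hand-implemented standard update, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) at a **fixed** learning rate, no
schedule or clipping, for a fixed number of epochs (default 10), batching
proteins with zero-padding and a validity mask. Gradients are exact
reverse-mode derivatives of the full objective — through the head,
attention softmax, GCN propagation, ReLU MLP and the contrastive cosines —
and the test suite verifies them against central finite differences of an
independently composed forward pass. The default learning rate is $10^{-4}$
with batch size 8; preset combinations mirror the protocol the model family
was introduced with (8e-5/batch 4, 8e-4/batch 4, 1e-4/batch 8, 1e-4/batch
512, chosen per data set scale).

The best epoch maximizes a selection metric (accuracy for classification,
Pearson for regression), with ties going to the earliest epoch. By default
selection happens on the **validation** split. The protocol of reporting
the test performance of the epoch that is best *on the test set* is
supported behind `selection_split = "test"` (CLI: `--paper-protocol`), with
an explicit warning: it reproduces the published protocol without silently
endorsing the leakage it entails.

All randomness — initialization, shuffling, contrastive sampling — descends
from the single `seed` in `train_config()`, so identical seeds give
bit-identical loss trajectories, and evaluation is deterministic.

## The synthetic generator

`synthetic_spec()` + `generate_dataset()` produce data whose signal
structure mirrors what the model is built to exploit, with every knob
explicit. Residue $i$ of type $a$ in a protein with class $c$ (or melting
temperature $t$) receives the embedding row

$$ p_i = \tau_a + \mu + \varepsilon_i, \qquad \varepsilon_i \sim \mathcal{N}(0, \sigma^2 I), $$

where the $\tau_a$ are fixed random unit vectors per amino-acid type scaled
by `residue_scale` (the signal the contrastive scheme can organize around),
and $\mu$ is a class prototype of norm $\delta$ (`effect_size`), or for
regression a fixed unit direction scaled by $(t - 45)/50 \cdot \delta$ — a
linear-in-temperature signal centered at the hot/cold boundary so that
rank-recovery tests have a known monotone target. The additive structure is
the simplest one that lets the sequence branch (type signal), the
contrastive scheme (type labels), and the prediction head (class signal) be
exercised independently. Contact maps combine a deterministic band
($|i-j| \le w$, default $w = 2$, chain locality) with sparse symmetric
long-range contacts (per-pair probability $\rho = 0.02$, weights uniform on
$[0.5, 1]$), diagonal zero. Classification targets are class-balanced to
within one protein; regression targets are drawn uniformly within the five
thermostability bands (balanced across bands, the open Hyperthermophilic
band capped at 95 °C for sampling); splits are 70/15/15 by protein.

What the generator does **not** emulate: the anisotropic, position-dependent
geometry of real PLM embeddings; correlations between sequence composition
and stability class; realistic contact topologies (secondary-structure
motifs, domain architecture); label noise. Passing the synthetic benchmarks
therefore demonstrates that the architecture, losses, gradients and
training loop are correct and that the model can extract a planted
sequence–structure signal — not that it attains any particular accuracy on
real proteomes.

`check_separability()` provides the baseline the trained model must beat: a
nearest-class-mean classifier on mean-pooled *raw* embeddings. At
$\delta = 0$ it sits at chance; at the benchmark SNR it is already high —
the benchmark validates machinery, not superiority over the baseline.

## Numerical choices

* Masked softmax uses $-\infty$ logits, so padded positions carry exactly
  zero attention; padding a batch never changes any protein's output
  (asserted to $10^{-10}$ in the tests).
* Cosine similarities of all-zero rows are defined as 0 with zero gradient.
  This makes the loss discontinuous exactly where a representation row is
  annihilated by ReLU — irrelevant in optimization (measure-zero set) but
  visible to finite-difference checks, which therefore use parameter draws
  whose activations are alive.
* RMSE is differentiated as a whole ($\partial \mathcal{L}/\partial
  \hat{t}_b = e_b / (B \cdot \mathrm{RMSE})$), with a zero gradient at the
  exact-fit point.
* AUC uses the Mann–Whitney half-credit tie convention, so an all-tied
  scorer yields exactly 0.5; the macro ROC curve averages per-class TPR on
  the union FPR grid. Spearman is computed tie-safely as Pearson on average
  ranks. $R^2$ may be negative for fits worse than the mean predictor and
  is reported as such.
* Argmax class prediction breaks ties toward the lower class index, making
  the zero-weight model's behavior (predict class 0 everywhere) exact.
* Class prototypes and residue-type vectors in the generator are random
  unit vectors, not an orthogonal design: at $F = 32$ their typical overlap
  is $O(1/\sqrt{F})$, small enough that the signal norms $\delta$ and
  `residue_scale` are interpretable.
* The dataset container is a single uncompressed serialized archive with a
  metadata table (id, target, split, task) and per-protein embedding and
  contact arrays; writing is deterministic, so equal seeds give
  byte-identical files.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `D` | 128 | width of both learned representations |
| `attn_groups` ($D''$) | 4 | independent attention views per branch |
| `adjacency_c` | 1e-6 | degree regularization in $\hat{\mathbf{A}}$ |
| `L_s` | 64 | residues sampled per protein for the contrastive term |
| `K` | 5 | negatives per anchor |
| `omega` | 0.5 | cosine scale, keeps similarities off the logistic saturation |
| `alpha` | 0.1 | weight of the contrastive term |
| `learning_rate` | 1e-4 | fixed Adam step size |
| `epochs` | 10 | training length; best epoch selected afterwards |

$\alpha$ has no published value; 0.1 keeps the contrastive term a
regularizer rather than the dominant objective at typical loss magnitudes
(cross-entropy near $\ln C$, contrastive near $2\ln 2$ at initialization)
and is flagged as unverified against the original. $L_s$, $K$ and $\omega$
likewise have no published values; $L_s = 64$ covers most proteins in the
synthetic regime entirely, and sampling is read as per-protein (the
per-mini-batch reading is the flagged alternative).

## Benchmark problem sizes

The package's own reference benchmarks — used by the test suite and by
`scripts/acceptance.R` — are sized for a laptop-class single CPU: binary
and five-class classification at $n = 200$ proteins of length 30–60 with
$F = 32$, $\delta = 3$, $\sigma = 0.5$; regression at $n = 300$ under the
same SNR. For these, the fitted width is $D = 32$ and optimization uses
learning rate $3 \times 10^{-3}$ at batch size 16 for 10 epochs: with
roughly 130 Adam steps, a step size in the $10^{-3}$ range is what moves a
freshly initialized head far enough to fit a high-SNR linear signal, while
the default $10^{-4}$ remains the conservative choice for long runs on
large corpora. Regression benchmarks enable target z-scoring
(`normalize_targets = TRUE`) so the head fits an $O(1)$ target rather than
temperatures spanning 115 °C; predictions are always returned in °C. Both
classification benchmarks are trained with the contrastive term off
($\alpha = 0$) and on ($\alpha = 0.1$) — the ablation axis of the
architecture — and must reach the same bar.

## Known limitations

* Dense linear algebra throughout: fine for proteins (hundreds to a few
  thousand residues), not intended for graphs orders of magnitude larger.
* No multi-task head (joint class + $T_m$), no per-class temperature
  calibration, no uncertainty quantification.
* Ten-fold cross-validation orchestration is not built in; the splits in
  the container are respected as given.
* The contrastive kernel question (cosine vs. scaled dot product) is
  settled by configuration, not by evidence from the original experiments.
* Real-data ingestion (HotProtein/DeepStabP-scale corpora, PLM embedding
  extraction) is out of scope by design; adapters can write the package's
  container format from any source.
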