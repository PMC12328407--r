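---
title: "Med-DGTN: model, design choices and numerical details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Med-DGTN: model, design choices and numerical details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Multi-label medical-image classification assigns a *set* of findings to each
image. Two structural facts distinguish it from generic multi-label work:
findings co-occur in clinically meaningful patterns, and the image evidence
for them is concentrated at low spatial frequencies (diffuse opacities,
drusen fields, vessel-calibre changes) on top of high-frequency acquisition
noise. Med-DGTN addresses both: a *dynamic* label-dependency graph feeding a
GCN that emits one classifier per label, and a wavelet-convolution backbone
biased toward low-frequency structure. This vignette records how each piece
is defined here, which choices were genuinely open, and what the bundled
experiments do and do not demonstrate.

## The label graph (DAME)

Statistics seed the graph. From binary annotations the co-occurrence counts
$M$ give the conditional probabilities $M'_{ij} = M_{ij}/M_{ii}$; we
condition **row-wise** ($M'_{ij} \approx P(j \mid i)$), the convention of
the ML-GCN line of work this construction descends from — the direction is
not dictated by the formula itself. Labels that never occur would divide by
zero; they instead get a zero off-diagonal row and a unit diagonal,
remaining isolated self-loop nodes rather than being dropped (matrix shapes
stay aligned with the label vocabulary).

Thresholding at $\tau$ (default 0.4, boundary maps to "edge kept") removes
low-confidence edges; reweighting gives every non-isolated node self-loop
weight $1-p$ and total neighbour mass $p$ (default 0.2), split evenly over
retained neighbours:
$N_{ij} = p\,A_{ij} / \sum_{j\ne i} A_{ij}$. The even split over *retained
neighbours only* is deliberate: a variant that normalises by a full column
sum would assign weight to absent edges, defeating the thresholding.
$p = 0$ yields the identity (pure self-connections); $p \to 1$ de-emphasises
the self-loop, risking the over-smoothing the reweighting exists to control.

### Attention refinement

Each of $k$ subgraph blocks (default $k = 2$) runs $h = 4$ scaled-dot-product
heads of dimension $d_h = 64$ over $N$, concatenates, and projects back to
$C \times C$. Two choices here were genuinely open:

* **Block/head structure.** The source formulation concatenates *all* heads
  into one matrix yet also takes a product over an index never fully
  pinned down. We read it as $k$ independent multi-head blocks, each
  emitting one subgraph $G_j$, composed left-to-right by matrix product
  $P = \prod_j G_j$. The product is order-sensitive; index order is the
  only defensible default. The attention is the scaled-dot-product form,
  not GAT-style additive attention, matching the printed equations.
* **Residual and initialisation.** We add $N$ as a residual around each
  attention block and zero-initialise the output projection $W_o$:
  $G_j = \max(N + \mathrm{Concat}(\text{heads})\,W_o,\, 0)$. At
  initialisation every $G_j$ equals $N$ exactly, so the refined graph
  *starts* as the statistics graph and training moves it away — the
  standard transformer residual convention. Without it, a random
  projection of $N$ scrambles the seeded structure, and recovering the
  planted co-occurrence blocks before any training would be a coin flip
  rather than a property of the design. Gradients reach $W_o$ immediately
  and reach $W_q, W_k, W_v$ from the second step on.

The product is rectified at zero and row-normalised before the GCN, whose
symmetric normalisation $\tilde D^{-1/2}\tilde A \tilde D^{-1/2}$ needs a
nonnegative adjacency; zero rows are left untouched (the GCN's $+I$
self-loop keeps their degree positive). $P$ is recomputed from the current
attention parameters on every forward pass rather than cached per epoch:
the graph is small ($C \times C$) and staleness buys nothing.

The attention stage computes $C^2 d$ weights (`complexity_estimate()`):
25,600 at $C = 20$, $d = 64$; 230,400 at $C = 60$.

## Label semantics

Label names are lowercased, tokenised on non-alphanumerics (hyphens split),
stop-word-filtered and Porter-stemmed (the stemmer is implemented in the
package and checked against published reference stems). A label whose
tokens are all stop words keeps its raw tokens — an empty node feature is
never produced. Node features are the **mean** of token vectors: graph
nodes are labels, the embedding table is per word, and the mean is the
minimal aggregation that stays in the embedding space.
Out-of-vocabulary tokens get a unit vector drawn from a generator seeded by
a hash of the token string plus the configured seed — deterministic across
runs and machines — and are reported in a warning. Cosine similarities of
the label embeddings are computed and exportable for inspection
(`label_cosine_matrix()`), but the default pipeline builds the graph purely
from co-occurrence statistics; `graph_init = "cosine"` optionally averages
in a cosine-derived edge graph. The two sources were never reconciled in
the source formulation; statistics-only is the reading consistent with its
pipeline figure.

The GCN stacks two layers, 300 → hidden → D, leaky ReLU (slope 0.2) after
the first layer only; the second layer is linear because its output *is*
the classifier. Hidden width defaults to 1024 in the full profile (between
the 300-dimensional input and D = 2048 output) and 64 in the reduced one.

## The image branch

WTConv decomposes the running low-frequency band level by level with the
orthonormal Haar transform (the family the wavelet-convolution literature
defaults to; no family was mandated), filters each of the four subbands
with small **depthwise** kernels — dense cross-channel kernels per subband
would contradict the "slight parameter increase" the construction is
prized for — and reconstructs upward, the deeper reconstruction taking the
LL slot. The reconstructed cascade is *added* to a depthwise base-conv
path; with identity (Dirac) kernels the layer returns exactly twice its
input, a property the tests exploit as a round-trip check. Orthonormality
makes every transform's adjoint its inverse, so backpropagation through
the cascade is again a pair of transforms.

Composite layers are BN → ReLU → 1×1 conv → WTConv. The 1×1 channel-mapping
convolution is an addition of ours: WTConv is channel-preserving, but a
dense-block composite layer must emit `growth` channels from a growing
input stack, exactly the role DenseNet's bottleneck plays. Four blocks of
six composite layers (growth 48, compression θ = 0.5) follow the
illustrated layout generalised to all blocks; since that schedule does not
naturally land on 2048 channels, a final 1×1 projection pins the output at
D = 2048 — our reconciliation of the DenseNet-style design with the printed
2048 × 14 × 14 map. The spatial schedule is exact: 448 → stem(÷4) → three
transitions(÷8) → 14.

Numerical conventions: reflection padding at every convolution, pooling and
wavelet boundary (replicate at the single-line pads of odd-sized maps),
avoiding dark-border artefacts; BN uses batch statistics in training and
running statistics in eval, with identity affine initialisation so tests in
eval mode are deterministic; max-pool ties resolve to the first window
position (ties have measure zero for continuous inputs).

## Training

SGD with momentum 0.9 and weight decay $10^{-4}$, two parameter groups —
graph branch (attention + GCN) and CNN branch — with separate learning
rates, both decaying to 1/10 of their **current** value every 30 epochs
(i.e. compounding ×0.1 at epochs 31, 61, 91), batch size 16, early
stopping with patience 10 on the monitored mAP (validation if provided,
else training) and best-weights restore. The loss is the negative Bernoulli
log-likelihood of the sigmoid logits, summed over labels and mean-reduced
over the batch, evaluated in the softplus form for numerical stability.

The reference learning rates (0.5 graph / 0.03 CNN) assume an
ImageNet-pretrained D = 2048 backbone and thousands of images. On the
reduced profile they diverge within a few epochs — gradients were verified
against finite differences, so this is conditioning, not implementation.
The reduced profile's preset therefore scales to 0.05 / 0.01, a choice we
made once for the profile and document here; `train_config()` itself keeps
the reference values.

Decision metrics threshold at 0.5 in sigmoid space (top-k was never
specified; 0.5 is the neutral choice and is configurable). F1 values are
harmonic means of the *aggregated* precision and recall. AP is the
all-points average over the descending ranking with stable tie-breaks; AUC
is the Mann–Whitney rank statistic with half-credit ties. Labels with no
positives (or one class, for AUC) are excluded from the mAP / mean-AUC
denominators and listed in the report rather than propagating NaN — small
splits hit this routinely.

## The synthetic generator

`synth_spec()` plants the two structures the model is built to exploit:
labels co-activate in blocks (a block is chosen uniformly per sample;
in-block labels activate with probability 0.6, out-of-block with 0.05;
all-zero rows are resampled), and each active label adds a broad Gaussian
blob (σ = image_size/10, amplitude 0.6) at a fixed grid position keyed by
the label index, plus i.i.d. pixel noise (σ = 0.05), clipped to [0, 1].
Fixed blob positions make each label linearly detectable, so an overfitting
check is meaningful. Default label names are distinctive single words:
shared tokens across labels would collapse the embedding matrix to
near-identical rows and with it the per-label classifiers — real disease
vocabularies are distinctive. The fixture embedding table gives each token
a seeded unit vector, plus a shared block component for tokens unique to
one block, so semantic similarity aligns with co-occurrence as it does in
real vocabularies. Everything is a pure function of the spec's seed.

What the generator does *not* emulate: anatomical backgrounds, inter-patient
variation, label noise, class imbalance beyond the block asymmetry, or any
photometric realism. Passing tests therefore demonstrate that the
machinery — graph construction, attention refinement, backprop through the
wavelet cascade, the dual-rate optimiser — is correct and trainable, not
that the model reaches any particular accuracy on real modalities.

## Experiment scale

The bundled experiments run at desk scale, chosen once: the reduced profile
uses 112-pixel images, a 16-channel stem, four 2-layer blocks (growth 8),
D = 128 and one wavelet level; structure-recovery runs use C = 8 labels and
n = 500 samples; the trainability check overfits 32 images for 30 epochs.
The 448-pixel default profile is exercised for its shape contracts (one
forward pass).

## Known limitations

* In the 32-image overfit regime the *learned* graph collapses to the
  identity: with every image memorisable per label, the co-occurrence prior
  carries no marginal information and training prunes the off-diagonal
  mass. Block structure in the refined adjacency is therefore a property of
  the statistics-seeded initialisation (where the tests assert it), not of
  the overfit endpoint; demonstrating that training *retains* useful graph
  structure needs data volumes where label correlations actually help
  generalisation.
* No pretrained backbone weights are available to this implementation, so
  absolute accuracies on real benchmark datasets are out of scope.
* Pure-R execution favours clarity and verifiability over speed; the
  default profile is practical for forward passes and small fine-tuning
  studies, not for 100-epoch full-dataset training.
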