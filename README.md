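# meddgtn

Multi-label classification of medical images — retinal fundus photographs,
chest radiographs and the like — where a single image can carry several
co-existing findings, and where the findings are *not* independent:
drusen co-occur with age-related macular degeneration, cardiomegaly with
effusion. `meddgtn` implements **Med-DGTN**, a classifier that makes this
dependency structure a first-class, *learnable* part of the model, coupled
with a CNN backbone built on **wavelet convolutions** that emphasise the
low-spatial-frequency bands where anatomical and pathological structure
lives.

The package is a complete, self-contained R implementation: every layer has
a hand-written forward *and* backward pass (verified against finite
differences), so the full network is trainable with plain R + BLAS — no
deep-learning framework required. A seeded synthetic-data generator with
planted label co-occurrence blocks makes the entire pipeline exercisable
end-to-end with no downloads.

## The model

**Dynamic label graph (DAME).** From the binary training annotations, count
the label co-occurrence matrix `M` (`M[i,j]` = images carrying both labels,
diagonal = per-label totals), condition it row-wise into
`M'[i,j] = P(label j | label i) = M[i,j] / M[i,i]`, threshold away
low-confidence edges,

    A[i,j] = 1  if M'[i,j] >= tau,   0 otherwise        (tau = 0.4)

and reweight to balance self-loops against neighbour mass:

    N[i,i] = 1 - p,    N[i,j] = p * A[i,j] / sum_{j!=i} A[i,j]    (p = 0.2)

A multi-head graph transformer then refines `N`: each of `k` blocks computes
`h` scaled-dot-product heads `softmax(Q K' / sqrt(d_h)) V` with
`[Q,K,V] = N [Wq, Wk, Wv]`, concatenates them, projects back to `C x C`
(with a residual on `N` and a zero-initialised projection, so the refined
graph *starts* at the statistics and moves away during training), and the
blocks are composed by matrix product into the adjacency `P`.

**Label semantics.** Label names are tokenised, stop-word-filtered and
Porter-stemmed; each label's node feature is the mean of its tokens'
300-dimensional GloVe vectors. A two-layer GCN over `P` (symmetric
normalisation with self-loops, leaky-ReLU between layers) maps these
embeddings to one linear classifier row per label: `W ∈ R^{C x D}`.

**Image branch.** A DenseNet-style backbone whose composite layers are
BN → ReLU → WTConv: a depthwise base convolution plus a cascaded Haar
decomposition that filters each frequency subband with small per-channel
kernels and reconstructs — widening the receptive field cheaply and
favouring low frequencies. A 448×448 input passes a 7×7 stride-2 stem, four
six-layer WTDense blocks with three transition layers, and a 1×1 projection
to a `2048 × 14 × 14` map, pooled to the image feature `x ∈ R^2048`.

**Fusion and loss.** Per-label logits are `y_hat = W x`; training minimises
the multi-label sigmoid cross-entropy with SGD (momentum 0.9, weight decay
1e-4, separate learning rates for the graph and CNN branches, step decay
×0.1 every 30 epochs, early stopping on mAP).

## Worked example

```r
library(meddgtn)

# seeded synthetic data: 8 labels in two co-occurrence blocks of four
spec <- synth_spec(C = 8, n = 500, blocks = 2,
                   p_within = 0.6, p_between = 0.05, seed = 11)
ann  <- sample_labels(spec)

g <- correlation_graph(ann, tau = 0.4, p = 0.2)
g$M[1:4, 1:4]
#>       alpha beta gamma delta
#> alpha   185   89   103   107
#> beta     89  151    85    87
#> gamma   103   85   168    94
#> delta   107   87    94   169

P <- dame_forward(g$N, dame_params(C = 8, seed = 11))
round(P[1:4, c(1:2, 5:6)], 3)
#>       alpha  beta epsilon zeta
#> alpha 0.653 0.116       0    0
#> beta  0.116 0.653       0    0
#> gamma 0.116 0.116       0    0
#> delta 0.116 0.116       0    0
```

The diagonal of `M` holds per-label totals; within-block pairs (e.g.
alpha–beta, 89 of 500 images) co-occur far more often than the cross-block
rate. After thresholding, reweighting and attention refinement, the
adjacency `P` is row-stochastic with strong self-loops (0.653), uniform
within-block edges (0.116) and no cross-block edges — the planted structure,
recovered.

Training the reduced 112-pixel profile on 32 synthetic images overfits as a
trainability check (about two minutes on one CPU):

```r
ds  <- make_dataset(synth_spec(C = 8, n = 32, seed = 7))
emb <- make_embeddings(ds$spec$labels, seed = 7, blocks = ds$spec$blocks)
cfg <- meddgtn_config("test", seed = 7); cfg$train$epochs <- 30; cfg$train$seed <- 7
fit <- train(meddgtn(ds$annotations, emb, cfg),
             list(images = ds$images, y = ds$annotations), cfg$train)
fit$best_map
#> [1] 99.44268
```

A shell interface wraps the same functions (`exec/meddgtn`):

```sh
meddgtn synth --n 32 --labels 8 --seed 7 --out data/
meddgtn build-graph --annotations data/labels.csv --out graphs/
meddgtn train --data data/ --out run/
meddgtn eval --checkpoint run/checkpoint.rds --data data/
```

`build-graph` exports `M`, `M'`, `A`, `N` and `P` as labelled CSVs plus a
heatmap PNG of `P`.

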