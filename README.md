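# eegdgcn

Emotion decoding from multichannel EEG with a **dynamic graph convolutional
network**: differential-entropy band features on the 62-electrode montage,
spectral graph convolution over a **learnable** channel-connectivity
adjacency, a style-recalibrated convolutional stack, multi-level feature
fusion, and post-hoc interpretation of the learned brain connectivity. The
package is aimed at researchers who work with segment-wise EEG band
features (the de-facto format of the 62-channel emotion corpora) and want a
fully inspectable, dependency-light R implementation of this model family —
every forward and backward computation is plain R, verified against
independent spectral and finite-difference oracles.

## The model

Each 1 s segment is a node-feature matrix `X ∈ R^{n×f}` (n = 62 channels,
f = 5 bands) of differential entropy

    h = 1/2 · log(2πeσ²)   (nats; σ² = band-limited segment variance)

over delta (1–4), theta (4–8), alpha (8–12), beta (12–30) and gamma
(30–64 Hz). Channels form a graph whose adjacency is initialized from
functional connectivity — `A_ij = |PCC(x_i, x_j)|` by default, PLV or
Uniform(0,1) alternatively — and then **trained jointly with the network**
by Adam. The forward pass:

    H1 = LeakyReLU(D̃^{-1/2} Ã D̃^{-1/2} X  W1)    (n×16),  Ã = |A| + I
    H2 = LeakyReLU(D̃^{-1/2} Ã D̃^{-1/2} H1 W2)    (n×64)
    p1 = sum-pool(H1) (16);  p2 = sum-pool(H2) (64)
    grid = reshape(p2, 8×8×1)
    conv 2×2 → (7,7,16) → SRM → conv 2×2 → (6,6,32) → SRM → maxpool → (3,3,32)
    F = [p1, p2, flatten] ∈ R^368 → FC 256 → 128 → softmax(C)

SRM ("style-based recalibration") gates each feature map by a sigmoid of a
batch-normalized linear function of its spatial mean and standard
deviation. Training minimizes cross-entropy + α‖Θ‖² with trial-based
train/test splits (first 9 of 15 trials train / last 6 test, or 16/8 for
4-class sessions). After training, the learned adjacency is min-max
normalized to [0,1] and its strongest connections are reported on named
10-20 electrodes, split into local (same scalp region) and global edges.

Because the real 62-channel emotion corpora are access-restricted, the
package ships a first-class synthetic generator: per-class ground-truth
connectivity graphs drive either raw multichannel signals (band-limited
sources mixed through a matrix square root of the graph) or DE-style
feature draws, so every stage — including recovery of the generating graph
by the learned adjacency — is testable end to end.

## Worked example

```r
library(eegdgcn)

spec <- synthetic_spec(segments_per_trial = 120, seed = 5)   # 62 ch, 3 classes
data <- generate_featureset(spec)                            # 1800 segments
sp   <- split_trials(data$featureset, 9)                     # 9/6 trial split

fit <- dgcn_fit(sp$train, dgcn_control(epochs = 5, seed = 2,
                                       l2_include_adjacency = FALSE))
fit
#> Dynamic-graph convolutional EEG emotion classifier
#>   channels: 62   bands: 5   classes: 3
#>   GCN widths: 16 -> 64   SRM: on   fused width: 368
#>   adjacency init: pcc   epochs trained: 5
#>   final training loss 2.2809, accuracy 0.901

evaluate_model(fit, sp$test)$accuracy
#> [1] 0.8972222

top_edges(fit, k = 5)
#> Top 5 connections (learned adjacency):
#>   channel_i channel_j weight local
#> 1        F6        T8 1.0000 FALSE
#> 2        O1        P8 0.9897 FALSE
#> 3        P4       TP7 0.9311 FALSE
#> 4       FC6        P3 0.9010 FALSE
#> 5       PO3       POZ 0.8816  TRUE
```

Test accuracy of 0.897 against a chance level of 1/3 shows the model has
learned the class structure; the edge table names the strongest learned
connections (weights min-max normalized to [0,1]) and whether each is a
local (within-region) or global connection. `asymmetry_delta()` tabulates
how training moved each edge away from its functional-connectivity
initialization, and `coef(fit)` returns the learned adjacency matrix.

A command-line front end over the same functions is installed at
`inst/cli/eegdgcn.R` (`simulate`, `extract-features`, `init-graph`,
`train`, `top-edges`).

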