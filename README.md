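# m6afuse

Deep sequence classification of RNA N6-methyladenosine (m6A) regions in
R.  `m6afuse` is aimed at computational epigenomics work on plant (rice,
maize) m6A-seq data, where methylated regions arrive as *variable-length
peak sequences* (20–800 nt) labelled positive (contains an m6A site) or
negative, typically at a 1:2 class ratio.  The package implements an
end-to-end convolutional architecture for this setting, a planted-motif
synthetic data generator so every stage is testable without external
downloads, cross-validated evaluation, and gradient-saliency motif-window
extraction.

## The model

Sequences are label-encoded and left-padded to a common length
(`P,A,T,G,C → 0,1,2,3,4`; `"ATTCG"` at `L_max = 10` becomes
`0 0 0 0 0 1 2 2 4 3`), embedded (the padding code maps to a fixed zero
vector), and passed through:

1. **Multi-kernel feature fusion (MKFF)** — four parallel 1-D conv paths
   over the projected embedding (kernel 1; bottleneck + kernel 3;
   bottleneck + kernel 5; max-pool + kernel 1), concatenated and mixed
   point-wise, then fused by **global–local dynamic attention**: a
   sigmoid-gated per-channel weight from efficient channel attention with
   adaptive kernel size

   $$k_{adp} = \left|\tfrac{\log_2 C}{\gamma} + \tfrac{b}{\gamma}\right|_{odd},
   \qquad \gamma = 2,\; b = 1,$$

   and a softmax-normalised per-position weight from a squeeze–excitation
   bottleneck (reduction ratio r = 4), combined point-wise with a
   residual connection back to the embedding.
2. **Downsampling residual feature embedding (DRFE)** — an equal-length
   two-conv stem followed by three downsampling residual blocks
   (stride-2 max-pool + equal-length double conv + skip), shrinking 800
   positions to 100.
3. **Sigmoid head** on the flattened embedding; probability ≥ 0.5 is
   called positive.

Training minimises `L_total = L_cl + L_bce`: mean binary cross-entropy
plus a margin contrastive loss `½[(1−K)D² + K·max(0, M−D)²]` (margin
M = 2) on flattened embeddings over seeded minibatch pairs, optimised
with Adam under full seed control.  Forward and backward passes are
written in the package (RcppArmadillo im2col + GEMM kernels) and verified
against finite differences and explicit-loop oracles in the test suite.
Ablation switches reproduce the no-MKFF / no-DRFE / no-contrastive
variants, the fusion variants (`cat`, `add`, `global`, `local`) and
kernel-subset combinations.

## Worked example

A small self-contained study — generate planted-motif data, train a
compact model, evaluate, and ask the saliency machinery where the model
looked (about a minute on one CPU):

```r
library(m6afuse)

cfg  <- m6a_config(L_max = 100L, embed_dim = 8L, out_channel = 16L,
                   n_dr_blocks = 2L, batch_size = 16L, epochs = 5L,
                   lr = 3e-3, seed = 1L)
recs <- generate_dataset(synthetic_spec(n_pos = 150L, n_neg = 300L,
                                        length_range = c(20L, 100L),
                                        seed = 1L))
sp    <- train_val_split(recs, 0.2, seed = 1L)
model <- train_model(build_model(cfg), sp$train, sp$val)

predict(model, sp$val[1:3])
#>          id probability label
#> 1 pos_00002   0.5657028     1
#> 2 pos_00004   0.6071241     1
#> 3 pos_00011   0.6725768     1

vb <- batch_encode(sp$val, cfg$L_max)
m  <- compute_metrics(vb$labels, predict(model, sp$val)$probability)
#> validation: ACC 0.9111  MCC 0.7974  AUC 0.9461  AUPR 0.9328

sal <- saliency_windows(input_saliency(model, sp$val[[1]]), window = 10)
head(sal[[1]]$windows, 2)
#>      start end    score
#> [1,]    25  35 3.525703
#> [2,]    15  25 1.405094
sp$val[[1]]$motif_intervals
#>      start end
#> [1,]    27  32
```

The metrics say the compact model separates motif-bearing from background
sequences well (AUC 0.95); the top-scoring saliency window `[25, 35)`
covers the planted motif at `[27, 32)` — the gradient points at the
signal the model actually used.

A command-line wrapper covers the same pipeline
(`simulate`, `train`, `cv`, `predict`, `interpret`, `grid`):

```sh
Rscript inst/scripts/m6afuse simulate --n-pos 100 --n-neg 200 --seed 1 --out data/demo
Rscript inst/scripts/m6afuse cv --fasta data/demo.fasta --folds 5 --out results/cv
```

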