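# bwenet

Prediction of post-translational modification (PTM) at the **center residue
of a fixed-length peptide window**, built for cysteine S-carboxyethylation —
a recently described modification of the cysteine thiol implicated in
autoimmune disease — but applicable to any centered-residue PTM. It is aimed
at computational biologists who have (or can extract) labeled peptide
windows and want a fully scripted, deterministic train/evaluate pipeline in
R.

## The method

Each candidate site is a window of `L` residues (default `L = 41`) with the
modified residue, e.g. cysteine, fixed at the center. Two ideas are
combined:

**Binary-Weight Encoding (BWE).** Position `i` of the window is one-hot
encoded over the alphabet `ACDEFGHIKLMNPQRSTVWY` (row `B_i`), then scaled by
an exponentially decaying positional weight

```
W_i = p · exp(−α · d_i),     X_i = B_i · W_i
```

where `d_i` is the distance (in residues) of position `i` from the window
center, `α ≥ 0` the decay coefficient (default 0.02) and `p > 0` the source
strength (default 1). `α = 0` recovers plain one-hot encoding, so the
unweighted representation is the special case, not a different method.
Residues near the modified site — where the discriminative composition is
concentrated — enter the network with proportionally larger magnitude.

**A CNN–BiLSTM–attention classifier.** The encoded `L × 20` matrix passes
through two 1-D convolutions and a max-pool (local motifs), a bidirectional
LSTM (context in both directions, hidden states concatenated per timestep),
additive Bahdanau-style attention

```
score_t = vᵀ tanh(w₁·O_t + w₂·H),    a = softmax(score),    C = Σ_t a_t O_t
```

over the retained timesteps `O_t` (with `H` the concatenated final hidden
states), and two dropout-regularized fully connected layers with a softmax
head. The network — forward pass, hand-derived backpropagation and Adam —
is implemented natively in RcppArmadillo; a seed fully determines
initialization, batching, dropout and therefore the fitted model. The
attention weight vector `a` is exposed per window, and the package can test
the model-interpretation claim that learned attention mirrors the BWE decay
curve, via dynamic time warping (DTW) of the stretched mean attention
profile against the positional weight curve.

Alongside the core model the package provides: plain binary, EAAC, DPC, TPC
and CTD comparison encoders; FASTA reading and window extraction; balanced /
imbalanced dataset assembly with exact-duplicate removal; grouped k-fold
cross-validation (all windows of one parent protein stay in one fold);
Sn/Sp/ACC/MCC, AUROC and AUPR; Mann-Whitney U model comparison; classical
baselines (RF/SVM/XGBoost) over flattened encodings; a seeded synthetic
window generator with a tunable center-concentrated signal; and t-SNE
embeddings of per-stage features.

## Worked example

```r
library(bwenet)

# a synthetic benchmark: 41-mers, signal residues K/R/E enriched near the
# center of positives with strength 0.8 decaying at 0.05 per residue
ds <- generate_dataset(signal_spec(seed = 1), n_pos = 600, n_neg = 600)
ds
#> window_dataset: 1200 windows (L = 41), 600 positive / 600 negative, 50 proteins

net <- model_config(conv_channels = c(8, 16), lstm_hidden = 16,
                    attention_dim = 16, fc_sizes = c(32, 16), dropout = 0.3)
enc <- encoding_config(alpha = 0.02, L = 41)

cv <- cross_validate(ds, net, enc,
                     train_spec(epochs = 20, seed = 1, early_stopping_patience = NULL),
                     k = 5, repeats = 1)
cv
#> 5-fold cross-validation, 1 repeat(s), encoder 'bwe'
#>   sn     0.9950 ± 0.0041
#>   sp     0.9967 ± 0.0041
#>   acc    0.9958 ± 0.0037
#>   mcc    0.9917 ± 0.0075
#>   auroc  0.9999 ± 0.0001
#>   aupr   0.9999 ± 0.0001
```

Accuracy ~0.996 and AUROC ~1 say the grouped CV recovers the planted
center-concentrated signal almost perfectly at this signal strength; the
`± SD` is the population spread over the five held-out folds. Training a
single model and comparing its attention profile to the encoding's
positional weight curve:

```r
m <- train_model(build_model(net, L = 41, seed = 1), ds, enc,
                 train_spec(epochs = 20, seed = 1, early_stopping_patience = NULL))
compare_attention_to_position_weights(m, ds, enc)
#> attention vs position-weight curve: DTW 0.08372 (normalized 0.00144);
#> vs rank-reversed curve: normalized 0.00356
```

The mean attention profile (stretched from the 16 retained timesteps to the
41 window positions) is closer, in normalized DTW distance, to the
center-peaked decay curve than to the same curve with its ranks reversed
(center-lowest): the attention mechanism allocates weight the way the
encoding assumes importance decays.

A command-line interface wrapping these functions ships in
`inst/cli/bwenet.R` (subcommands `simulate`, `encode`, `train`, `cv`,
`evaluate`, `analyze-attention`, `sweep`, `tsne`, `rerun`); every command
writes a `manifest.json` from which `rerun` reproduces its numeric outputs
byte-for-byte.

## Package layout

- `R/windows.R` — FASTA input, window extraction, dataset assembly, grouped folds
- `R/encoding.R` — BWE, binary, EAAC, DPC, TPC, CTD encoders
- `src/nn.cpp` — the CNN–BiLSTM–attention network (forward, backprop, Adam)
- `R/model.R`, `R/training.R` — model configuration, training, CV, metrics, baselines
- `R/attention.R` — attention profiles, stretching, DTW comparison
- `R/synthetic.R` — the synthetic center-signal generator
- `R/tsne.R`, `R/cli.R` — stage-feature embedding, command implementations
- `vignettes/bwenet-methods.Rmd` — the model, its assumptions and design choices
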