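---
title: "Binary-weight encoding and the attention classifier: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary-weight encoding and the attention classifier: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
benchmark does and does not establish, and the places where the design was
genuinely open and a choice had to be made.

## The prediction problem

The unit of analysis is a peptide window: `L` consecutive residues of a
protein with a candidate modified residue — cysteine, for the
S-carboxyethylation case this package was built around — fixed at the
center position `(L+1)/2`. The classifier sees only the window; everything
the model can learn is the local sequence context of the candidate site.
The biological premise is that the residues relevant to whether a site is
modified are concentrated near the site itself, and that their relevance
decays with distance. Windows at protein termini are padded with `X`, which
every encoder maps to an all-zero row, so truncation never invents
composition.

## Binary-weight encoding

Position `i` is one-hot encoded over `ACDEFGHIKLMNPQRSTVWY` and scaled by

$$W_i = p\,e^{-\alpha d_i}, \qquad X_i = B_i W_i,$$

with $d_i = |i - \text{center}|$ in residue units.

* `alpha` (unitless, per residue; default **0.02**) controls how fast
  positional weight decays. At `alpha = 0.02` and `L = 41` the edge
  positions ($d = 20$) still carry weight $e^{-0.4} \approx 0.67$: the
  decay is a soft prior, not a hard mask. The default is the value at
  which 41-mer models performed best in the work this method comes from;
  `cli_sweep()` re-runs that comparison (including the `alpha = 0`
  unweighted control, which is exactly plain binary encoding) on synthetic
  data.
* `p` (unitless; default **1**) scales every feature uniformly. Only the
  product $p\,e^{-\alpha d}$ enters the features, so `p` is a
  convenience for downstream scaling, not a shape parameter; tests assert
  `bwe(p = c)` is `c` times `bwe(p = 1)` exactly.
* `L` (residues; default **41**, odd) is the window length.

The comparison encoders (EAAC with a 5-residue subwindow, DPC, TPC, CTD
with the standard 7-attribute/3-group physicochemical classification) are
implemented from their usual definitions; `X` is excluded from all counts
(both numerator and denominator for compositions; k-mers containing `X`
are skipped).

## The classifier

The stack is: two 'valid' (unpadded) 1-D convolutions with ReLU, a
non-overlapping max-pool, a BiLSTM whose per-timestep forward and backward
hidden states are concatenated, additive attention, then two
dropout-regularized fully connected ReLU layers and a softmax over the two
classes. With the default kernel sizes (5, 5) and pool width 2, a 41-mer
yields 16 retained timesteps. Cross-entropy is minimized by Adam
(default learning rate 1e-3, batch 64). All sizes are configuration, not
architecture: the original description fixes the layer types but not their
widths, so `model_config()` defaults (channels 32/64, LSTM hidden 64,
attention 64, FC 64/32, dropout 0.5) are package choices, and the shipped
analyses use a deliberately small variant (8/16, 16, 16, 32/16, dropout
0.3) that recovers the synthetic signal while keeping a full
cross-validation run in seconds.

The attention stage computes, per retained timestep $t$,

$$\text{score}_t = v^\top \tanh(w_1 O_t + w_2 H),$$

softmax-normalizes the scores into weights $a_t$ and returns the context
$C = \sum_t a_t O_t$ along with $a$ itself. Two points here were genuinely
open:

* **What is $H$?** The attention formulation speaks of a decoder state,
  but a classifier has no decoder. We use the concatenated final
  forward/backward hidden states of the BiLSTM — the only summary state
  the architecture offers. When the BiLSTM is ablated away, $H$ falls back
  to the mean convolutional feature.
* **Where does attention look?** We attend over the pooled convolutional
  timesteps as processed by the BiLSTM (16 for the default 41-mer), not
  over the 41 raw positions; the profile is mapped back to sequence length
  by stretching (below).

Architecture ablations (CNN-only, BiLSTM-only, CNN-BiLSTM without
attention) are pure configuration flags, so model-architecture comparisons
are run from config, with the Mann-Whitney U test (`mann_whitney_compare()`)
for per-fold metric differences. When attention is disabled the per-window
"attention" output is the uniform vector, keeping the interface stable.

## Numerical and initialization choices

* Weights are Glorot-uniform from a dedicated seeded generator; biases are
  zero, *including the LSTM forget gate*. Starting with forget gates at
  sigmoid(0) = 0.5 makes the recurrence begin with short memory, so early
  in training each timestep's hidden state mostly reflects its local
  neighborhood and timesteps retain positional meaning for the attention
  stage; memory lengthens as training demands it.
* Softmaxes subtract the row maximum before exponentiation; attention
  weights are therefore invariant to adding a constant to all scores
  (asserted in tests at 1e-6).
* Dropout is inverted (scaling at train time), disabled at evaluation:
  evaluation-mode forward passes are bitwise reproducible.
* The decision threshold for confusion counts is 0.5; a score exactly at
  the threshold is called negative (ties resolve toward class 0).
* A zero denominator in Sn, Sp or MCC yields 0 plus a flag naming the
  affected metric, rather than NaN. Note that the all-wrong classifier
  (TP = TN = 0 with both FN, FP > 0) has a well-defined MCC of −1 — only
  tables with an empty margin are flagged.
* AUROC is computed by the rank formula (equivalent to trapezoidal ROC
  with tied scores rank-averaged); AUPR by step interpolation with tied
  scores processed as a single threshold.
* DTW uses the classic steps (1,0), (0,1), (1,1) with cost
  $|a_i - b_j|$ and no window constraint; the backtrace breaks ties
  deterministically (diagonal, then vertical, then horizontal). Tests
  check it against exhaustive enumeration of all monotone paths.
* Attention profiles are stretched to sequence length by linear
  interpolation of the `T` values at positions mapped uniformly onto
  `[0, L-1]`, then renormalized. Repetition and zero-padding were the
  alternatives; interpolation is the only one of the three that is
  order-preserving, leaves constant profiles constant, and introduces no
  artificial steps. Compression (`L < T`) is refused.
* The reversed reference curve in
  `compare_attention_to_position_weights()` reassigns the position-weight
  values so their ranks are mirrored (center-lowest, same value multiset),
  which is a sharper contrast than flipping the curve left-to-right —
  a symmetric curve is its own mirror image.

## Cross-validation and evaluation protocol

Folds are grouped by parent protein: a greedy partition (largest protein
first into the currently smallest fold, seeded shuffle for ties) ensures no
protein contributes windows to both a training and its validation split,
the analogue of requiring no overlapping proteins between validation sets.
Each fold's model is rebuilt and retrained from scratch; no early stopping
is used inside cross-validation, because the only held-out data is the fold
being evaluated (early stopping with a user-supplied validation set is
available in `train_model()`). The reported `± SD` is the population
standard deviation across all fold-by-repeat evaluations.

## The synthetic benchmark

`generate_dataset()` emulates the structure the method assumes real PTM
window data to have: positives carry a compositional signal — enrichment of
`signal_residues` (default K, R, E) — whose per-position probability is
$s_0 e^{-\beta d}$, strongest adjacent to the center and decaying with
distance; negatives are i.i.d. background (default uniform). Windows are
attributed round-robin to synthetic proteins so grouped CV is exercised.
The generator's decay $\beta$ is deliberately a different parameter from
the encoder's $\alpha$, so recovery experiments can ask whether weighting
helps without the generator and encoder sharing a dial. The analytic
per-position signal frequency (`expected_signal_frequency()`) serves as the
closed-form oracle for validating the generator itself.

The shipped analyses (test suite and `scripts/acceptance.R`) run at: 600
positives + 600 negatives, `L = 41`, $s_0 = 0.8$, $\beta = 0.05$, 50
proteins; grouped 5-fold CV with the small architecture and 20 epochs, five
seeds for the BWE-vs-binary comparison and three for the attention-DTW
comparison. At these settings one full cross-validation takes on the order
of ten seconds.

What passing these analyses shows: the pipeline end-to-end can detect a
center-concentrated compositional signal almost perfectly, weighted
encoding does not hurt and (weakly, at this easy signal strength) helps,
and the learned attention profile resembles the assumed positional decay
more than its inversion. What it does not show: performance on real
proteomes. The generator has no homology structure between proteins, no
realistic background composition, no motif syntax (signal residues are
exchangeable), and no label noise — real S-carboxyethylation data are
harder in all four ways, and headline numbers on the synthetic benchmark
are accordingly near-ceiling rather than realistic.

## t-SNE stage visualization

Per-stage features (encoding, post-CNN, BiLSTM summary, attention context)
can be embedded in 2-D for inspection. The package carries its own compact
exact (non-tree) t-SNE — perplexity-calibrated Gaussian affinities by
bisection, Student-t output kernel, momentum gradient descent with early
exaggeration — which is adequate for the few-thousand-window datasets this
package targets and is seeded/deterministic. It is a visualization aid only; nothing downstream
depends on it.

## Known limitations

* The network is CPU-only and processes windows one at a time inside each
  minibatch; it is sized for datasets of thousands, not millions, of
  windows.
* Sequence-identity clustering (CD-HIT-style) is out of scope: the package
  removes exact duplicates only and expects redundancy reduction upstream.
* The AAindex physicochemical encoder is not provided (it requires an
  external index database); EAAC/DPC/TPC/CTD cover the comparison space.
* `p` in the encoding and the softmax temperature are redundant with
  downstream scales and are kept only for fidelity to the formulation.
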