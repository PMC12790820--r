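---
title: "Partitioning PLM embeddings into informed and residual subspaces"
author: "plmx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning PLM embeddings into informed and residual subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plmx)
```

## The model

Protein language models produce one embedding vector per residue
(width D = 480 for ESM2-35M, 1280 for ESM2-650M, 1024 for ProtBert).
`plmx_adapter()` fits an encoder–decoder that re-expresses each vector
as a concatenation of an *informed* part — 34 dimensions trained to
equal handcrafted biochemical features — and a *residual* part of
width D − 34 that keeps whatever else the embedding encodes.

The 34-dimensional layout is fixed package-wide
(`feature_layout()`): SS3 one-hot (3), SS8 one-hot (8), ASA in Å² (1),
Kyte–Doolittle hydropathy (1), an aromaticity indicator over
{F, W, Y} (1), and the amino-acid one-hot (20). SS3 is always the
standard reduction of SS8 (H,G,I → H; E,B → E; T,S,"-" → C).

Architecture, per residue embedding x of width D:

* informed branch: `affine(D→D) → ReLU → affine(D→34) → Tanh`, then one
  learned positive scale per feature task. The scale lets bounded Tanh
  outputs reach unbounded targets (ASA spans hundreds of Å²); it is
  initialized at 1 for classification tasks and at the training-set
  maximum absolute target for the L1 tasks, and kept positive through a
  log parameterization. Classification tasks read their slice of the
  34 outputs directly as logits, so one 34-wide layout is shared by the
  informed head and the adversaries.
* residual branch: `affine(D→D) → ReLU → affine(D→D−34) → Tanh`,
  without a scale. We experimented with a learned residual scale and
  found it gives the encoder a degenerate way to beat the adversaries —
  shrink the whole residual — which destroys reconstruction and any
  residual signal; the bounded Tanh is load-bearing.
* decoder: `affine(D→D) → ReLU → affine(D→D)` with a *linear* final
  layer. A terminal ReLU could not reconstruct negative embedding
  coordinates, so the second activation is deliberately omitted; this
  is the one intentional deviation from a literal two-ReLU reading of
  the architecture.
* adversarial heads, one per feature task:
  `affine(D−34→⌊D/2⌋) → ReLU → affine(⌊D/2⌋→34)`, of which only the
  task's slice enters its loss. The heads are attached to the residual
  through a gradient reversal layer (`grl_forward()` /
  `grl_backward()`): identity in the forward pass, gradient times
  −`grl_scale` in the backward pass. One joint Adam optimizer then
  trains the heads to *minimize* their feature-prediction loss while
  the encoder receives the reversed gradient and *maximizes* it — no
  alternating optimization is needed.

The objective is the weighted sum

L_total = λ_rec·L_rec + Σ_t λ_hcf(t)·L_hcf(t) + Σ_t λ_adv(t)·L_adv(t)

with L_rec the mean absolute error between the original and
reconstructed embeddings, cross-entropy for SS3/SS8/amino-acid,
binary cross-entropy for aromaticity and L1 for ASA and GRAVY.
`loss_total()` recomputes this sum exactly from a logged breakdown; the
training loop logs every step, and the identity is asserted to 1e-6
relative in the tests.

### Masking

Residues are excluded from the feature and adversarial losses when
their annotation is untrusted: pLDDT strictly below 0.7 (read from the
B-factor column of AlphaFold-style PDB/mmCIF files; values above 1 are
divided by 100), nonstandard amino acids (X, B, Z, U, O — masking them
keeps the one-hot invariant intact rather than inventing an all-zero
class), or missing DSSP coverage. The reconstruction loss uses *all*
residues: the embeddings themselves are trusted even where the
structural annotation is not. At transform time nothing is filtered.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_rec` | 1 | weight of the reconstruction MAE |
| `lambda_hcf` | 1 per task | informed-subspace feature losses |
| `lambda_adv` | 1 per task | adversarial suppression strength; the single knob of the trade-off sweep |
| `grl_scale` | 1 | gradient-reversal factor (the sweep is carried by `lambda_adv`) |
| `epochs`, `batch_size` | 30, 256 residues | Adam training schedule |
| `learning_rate` | 1e-3 | Adam step size, with a step decay (×0.3 after 60% and 85% of epochs) that damps the adversarial oscillation late in training |
| `clip` | 5 | global gradient-norm clip; keeps large reversed gradients from destabilizing training at `lambda_adv` = 10 |

λ = 1 is the operating point used throughout downstream evaluation:
reconstruction stays low while handcrafted features are partly
suppressed from the residual. Raising λ suppresses more and
reconstructs worse; suppression plateaus beyond λ ≈ 5.

A note on the learning rate: 1e-4 (a common default elsewhere) is far
too slow for this implementation's joint Adam — on the synthetic
recovery benchmark it reaches 59% SS8 accuracy where 1e-3 reaches
100% in the same 60 epochs — so 1e-3 is the default.

## What the synthetic generator emulates

`simulate_dataset()` builds a world in which every claim is checkable:
per residue an amino acid is drawn (hydropathy, aromaticity and the
one-hot follow), SS8 follows a three-state-biased Markov chain
(self-transition 0.85, helix/strand/coil emission to the eight fine
states), ASA is a state-dependent gamma (shape 2; mean 35/20/70 Å² for
H/E/C — buried strands, exposed coil), and an independent k = 8
dimensional latent u is drawn. The embedding is

x = A f + B u + ε,  ε ~ N(0, σ²), σ = 0.05 by default,

with A (D×34) and B (D×k) fixed full-column-rank Gaussian maps drawn
from named seeds. Inside the map the feature channels are scaled to
unit range (ASA/50, GRAVY/4.5) so no channel dominates the embedding;
annotations keep physical units. Because the map is linear, ridge
regressions and linear probes are closed-form oracles for everything
the adapter should recover. A 5% fraction of residues gets pLDDT drawn
in [0.30, 0.69] and deliberately garbled annotations, exercising the
masking path without dominating training.

The protein label defaults to `mean(u[,1]) > 0`, so it lives entirely
in the residual subspace and features predict it at chance. For
downstream-evaluation experiments the generator offers
`u_protein_weight`: a share w of a per-protein latent in
`u_i = sqrt(1−w²) e_i + w z`. A protein-*level* label needs a
protein-level latent — with i.i.d. per-residue noise the pooled signal
shrinks as 1/√L and no pooled model should be expected to carry it —
and PLMs do spread global sequence context over all residues. The
downstream world uses w = 0.7 and a label depending on both hydropathy
(informed) and u (residual).

What the generator does **not** emulate: the geometry of real PLM
embeddings (anisotropy, attention-induced correlation structure),
realistic sequence composition beyond uniform amino acids, and any
relationship between sequence and structure. A green test on this
world establishes that the machinery is correct and that the
qualitative trade-offs hold under a known ground truth — not that the
real-corpus error rates are reproduced.

## Downstream evaluation and interpretation

Four embedding variants are compared, all mean-pooled per protein for
the gradient-boosting path: `partitioned` (informed + residual, width
D), `original` (raw embeddings), `informed` (34 columns), and
`crafted_only` — the informed subspace with each multi-class block
collapsed to the one-hot of its argmax (ties to the lowest index,
aromaticity thresholded at probability 0.5, continuous channels passed
through), emulating a classical discrete-feature pipeline. The pooled
classifier is gradient-boosted trees (100 iterations, depth 4,
learning rate 0.05, logistic loss with Newton leaf values). The local
path is a 1D CNN: 50 filters, kernel 6 (aggregation) or 8 (EV,
transmembrane), ReLU, max-pool over positions, dropout 0.2, one output
unit, Adam 1e-4, batch 16, at most 20 epochs with the best epoch
chosen by validation loss. Confidence intervals are 95% t-intervals of
the mean over 10 bootstrap rounds in which only the *training* data is
resampled; the test set stays fixed.

Residual suppression is validated exactly as in training-free probing:
a two-layer network (hidden ⌊D/2⌋, ReLU) is trained on the residual
vectors of the held-aside 5% probe split and evaluated on the test
split, per feature task.

`global_attribution()` computes exact path-dependent tree SHAP for the
boosting model — per-sample values sum to the log-odds output minus the
cover-weighted expectation, asserted to 1e-6 — and reports mean |SHAP|
per named feature; `top_feature_occurrence()` counts appearances in the
per-run top 10 across bootstrap refits. `local_filter_attribution()`
selects the most activated CNN filter (maximum single post-ReLU
activation; ties to the lowest index) and attributes its activation at
every window position to the input channels with a permutation Shapley
estimator whose reference is the background feature means (up to 100
background samples); per-position values sum exactly to activation
minus baseline. Positions below 10% of the maximum activation are
flagged low-confidence — attributions in weakly activated regions
should be read with caution.

## Numerical choices and degenerate inputs

* Argmax readouts break ties to the lowest class index, everywhere.
* CE/BCE use max-subtraction / `log1p(exp(−|x|))` stable forms.
* The L1 gradient at exactly zero error is 0 (`sign(0)`).
* A training batch whose residues are all masked is skipped; loss
  functions called directly on empty input raise "no residues to
  score".
* Non-finite training loss aborts with the offending epoch and batch.
* Sequences shorter than the CNN kernel are zero-padded to one window.
* An all-zero activation map still yields a filter report, flagged
  `all_zero`, with the filter chosen by tie-break.
* Embeddings are stored as R doubles; R has no 32-bit float type, so
  archives are double-precision and bit-exact on round trip.

## Design choices where the design was open

* **Per-task adversaries.** One head per feature task (rather than one
  shared 34-wide head), each outputting the full 34-wide layout with
  only its slice entering its loss; this couples every head to the
  shared feature geometry while keeping per-task λ knobs.
* **Raw ASA.** ASA is stored and predicted in Å², not as relative
  accessibility: the per-task output scale exists precisely to reach
  large numerical ranges.
* **Probe protocol.** The probe trains on the dedicated 5% split and
  is evaluated on the test split, so probe capacity never sees probe
  evaluation data.
* **Split proportions.** The held-out 5% is divided evenly into
  validation and test halves (validation first).
* **Best checkpoint** is chosen by validation L_total; the logged
  history keeps every step's breakdown so the choice is auditable.

## Known limitations

* At the adversarial operating point the reconstruction error on the
  small synthetic world (~0.25 MAE at λ = 1, D = 64) is far from the
  noise floor reachable at λ = 0 (< 0.05); the trade-off is real and
  the package reports it rather than hiding it. Within the test-suite
  budget the λ = 0 autoencoder reaches the injected-noise scale only
  on the noiseless world; on the σ = 0.05 world it plateaus slightly
  above (≈ 0.065 after 150 epochs).
* Adversarial suppression is partial, exactly as observed at λ = 1:
  the residual SS8 probe drops from ~0.87 to ~0.5, not to chance.
* The CNN is a single-layer detector; it is the evaluation protocol's
  model, not a state-of-the-art classifier.
* The residual subspace remains unnamed: its coordinates are reported
  as `feature_35 … feature_D` and interpretation stops at "not one of
  the 34 informed features".
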