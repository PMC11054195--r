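---
title: "Prototype learning for heartbeat classification: model, objectives, and editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype learning for heartbeat classification: model, objectives, and editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protobeat)
```

## The model and its assumptions

`protobeat` classifies fixed-length univariate time-series segments —
single heartbeats — by similarity to a small set of learned exemplar
patterns. The pipeline is

1. **Framing.** A beat of length `L` is cut into `T` contiguous frames of
   width `n = floor(L / T)`; trailing remainder samples are dropped so all
   frames are homogeneous. The default is `L = 180` samples (0.6 s at
   300 Hz) and `T = 18`, i.e. 10-sample (~33 ms) frames — roughly the
   width of a QRS complex, so a single deflection is localized in one or
   two frames.
2. **Encoding.** A stacked bidirectional LSTM (3 layers, 16 hidden units
   per direction by default) produces per-step states; with both
   directions concatenated the latent width is `u = 32`. Hidden states are
   products of a sigmoid gate and a tanh, hence every component lies
   strictly inside (−1, 1).
3. **Attention pooling.** Each state is scored as `Vᵀ(Wᵀh_t + b)`, the `T`
   scores are softmax-normalized into weights `α`, and the embedding is
   the convex combination `e = Σ_t α_t h_t`. The score is the plain
   bilinear form by default; a `score_tanh` switch inserts the
   conventional tanh between the two attention layers for users who want
   the saturating variant. Scoring is applied per step; this reproduces
   the intended shapes (`α ∈ R^T`, `e ∈ R^u`) without broadcasting
   ambiguity.
4. **Prototype layer.** `K` trainable vectors `p_k` live in the same
   latent space. Distances `d_k = ‖e − p_k‖₂` become similarities
   `s_k = exp(−d_k) ∈ (0, 1]`.
5. **Head.** Logits are the linear map `z = Ws` with `W ∈ R^{C×K}`,
   turned into probabilities by a softmax (the natural choice that stays
   well-defined for any `C ≥ 2`). No activation sits between `s` and `W`,
   and `W` is unconstrained — negative weights are allowed and simply mean
   a prototype argues *against* a class.

The model assumes beats are pre-segmented to a common length and that a
single beat carries enough morphology to classify (no RR-interval or
rhythm-sequence features; see Limitations).

### Distance conventions

The similarity distance is the *unsquared* L2 norm, while the three
regularizers below use *squared* norms. Both conventions are exposed
(`dist_squared` in `proto_model()`), with these defaults. This mixed
convention is deliberate: the exponential similarity stays
better-conditioned with the unsquared distance (its gradient does not
vanish at the prototype), while squared norms give the regularizers
smooth, cheap gradients.

## The training objective

```
Loss = CE + λ·R(P) + λ₁·R₁(P, X) + λ₂·R₂(P, X)
```

* **Cross-entropy** `CE = −Σ_i log probs_i[y_i]`, summed over the
  mini-batch (a `mean_ce` switch reports the mean instead). Probabilities
  are clipped to `[1e−12, 1 − 1e−12]` before the log.
* **Diversity** `R(P) = σ(threshold − min_{i<j} ‖p_i − p_j‖²)` penalizes
  the closest prototype pair, with threshold 1 (squared latent distance).
  The minimum is over unordered distinct pairs; for `K = 1` no pair exists
  and the term is 0. Near-coincident prototypes yield a near-zero
  gradient (the pair difference itself is the gradient direction), so the
  term separates close-but-distinct prototypes rather than splitting exact
  duplicates.
* **Prototypicality** `R₁ = Σ_k min_j ‖p_k − e_j‖²` pulls every prototype
  toward its nearest encoded instance, keeping prototypes representable by
  real beats.
* **Clustering** `R₂ = Σ_j min_k ‖e_j − p_k‖²` is the mirror term pulling
  instances toward the prototype set.

Default weights are `λ = 0.01`, `λ₁ = λ₂ = 0.05`. `R₁`/`R₂` are computed
on the mini-batch embeddings each step for tractability; a `reg_full_set`
switch recomputes them on the full training set for users who want the
literal full-dataset definition at desk scale.

### Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `n_steps` (T) | 18 | frames per beat; 10 samples ≈ 33 ms at 300 Hz |
| `hidden_size` | 16 | LSTM units per direction (u = 32 bidirectional) |
| `num_layers` | 3 | stacked LSTM layers |
| `d_alpha` | 16 | attention hidden width |
| `n_prototypes` (K) | 12 | prototypes for C = 3; pruning governs the final count |
| `dropout` | 0.1 | rate on the pooled embedding, before the prediction layers |
| `learning_rate` | 0.002 | Adam step size |
| `batch_size` | 128 | mini-batch size |
| split | 70/10/20 | stratified train/validation/test fractions |
| `λ, λ₁, λ₂` | 0.01, 0.05, 0.05 | loss weights |
| `diversity_threshold` | 1.0 | squared latent distance |
| `dmin` | 2.0 | candidate-filter distance (latent space) |
| `clip_norm` | 5.0 | global gradient-norm clip |

Dropout is applied only to the pooled embedding (the input of the
prediction layers), not inside the recurrent stack: the prediction layer
is where the regularization is wanted, and keeping the recurrence
deterministic makes per-step states reproducible for inspection. The
mask uses inverted scaling so inference needs no correction.

## Optimization and numerical choices

* **Initialization.** All weights are uniform in ±1/√(fan-in) from seeded
  streams. Prototypes are initialized to the embeddings of `K` randomly
  chosen training beats — stabler than a Gaussian start and already
  consistent with the prototypicality term.
* **Optimizer.** Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) with bias
  correction, single-threaded and fully deterministic given the seed; all
  randomness (splitting, initialization, shuffling, dropout) fans out
  from one run seed to named sub-seeds. Gradients are clipped at global
  norm 5 to prevent recurrent blow-ups; the clip can be disabled.
* **Gradients** are computed by hand-written reverse-mode passes through
  the whole pipeline (softmax/CE, head, similarity, distance,
  regularizers, attention, stacked bidirectional LSTM) and are validated
  against central finite differences in the test suite. At the
  non-differentiable points of the min-based regularizers the argmin
  branch's gradient is used; ties have measure zero under training noise.
  The unsquared-distance gradient divides by `max(d, 1e−12)` to guard the
  coincident case.
* **Model selection.** No early stopping; the state with the best
  validation accuracy is returned, with ties resolved toward the later
  epoch (later states have seen more optimization at equal validation
  evidence). The final-epoch state is also kept.
* **Ties.** Prototype class labels use the head-column argmax with
  lowest-class tie-breaking; an all-zero column is flagged degenerate.
  Projection ties go to the lowest training index.
* **Degenerate inputs.** Framing requires `T ≤ L`; `K = 1` models are
  legal everywhere except prototype removal; empty embedding or prototype
  sets are rejected by the regularizers with explicit errors.

## Interpretation and editing

Projection associates each prototype with its nearest training embedding
(exhaustive scan). *Snapping* — overwriting the vector by that embedding
so every prototype is exactly an observable waveform's image — is off
during training and applied for final reporting; the learned (unsnapped)
vectors remain the classifier, because snapping an undertrained prototype
can move it far. Explanations decompose the predicted logit exactly:
`z_c = Σ_k W[c,k]·s_k`, so the report's contribution column sums to the
logit to machine precision.

Editing operations keep the shape contract `K = ncol(W)` at every step:

* **filter-candidates** keeps signals whose minimum latent distance to all
  prototypes is ≥ `dmin` (the filter operates in embedding space, the only
  space prototypes exist in).
* **add** embeds a chosen beat as a new prototype with a zero head column,
  so predictions are provably unchanged until fine-tuning; exact
  duplicates (distance < 1e−9) are rejected.
* **validate** freezes the vector (excluded from gradient updates) while
  its head column still trains.
* **prune** scores each unvalidated prototype by leave-one-out validation
  accuracy — the most literal "contribution" measure and cheap at desk
  scale — and greedily removes non-contributing ones (ties broken toward
  the smallest head-column norm, i.e. the least influence on any logit),
  never dropping a currently-owned class's last prototype nor going below
  `C` prototypes.
* Every operation appends to a replayable JSON-lines edit log; replay on
  the same checkpoint reproduces count, metadata and (absent fine-tuning)
  predictions.

## The synthetic generator

The generator emulates the class phenomenology of single-lead
single-beat ECG at 300 Hz: normal beats as Gaussian P and T bumps around
a narrow biphasic QRS; AF beats with the P wave replaced by an
amplitude-modulated 5–9 Hz fibrillatory oscillation and wider QRS
amplitude variation; "other" beats with a widened, notched QRS and
inverted T. Gaussian-bump morphology was chosen over a dynamical ECG
model for transparency: every waveform is a closed-form function of its
recipe, so tests can assert class structure (e.g. AF recipes never
contain a P component) directly. White noise with `noise_sd = 0.03`
(relative to the unit-order QRS amplitude) reflects a clean, band-passed
recording.

What it does **not** emulate: baseline wander, electrode noise and the
"too noisy" class, beat-segmentation errors, RR-interval context,
inter-patient morphology drift, or class imbalance. Passing tests
therefore demonstrate that the implementation is correct and that the
method recovers a solvable, well-separated task; they do not certify
clinical performance on real recordings. The WFDB reader provides the
bridge to real single-lead data for users who have it; it is never
required.

Problem sizes used by the test suite and the acceptance script — 600
beats per class, 30 training epochs, 3 seeds for the stochastic checks,
and a 60-beat noise-free two-class fixture for exact contract tests — are
chosen as the smallest sizes at which the study's properties are stable.

## Known limitations

* Single-beat scope: no rhythm-level features (RR intervals, beat
  sequences), which matter for clinical AF detection.
* The encoder is a plain LSTM stack; no GRU or self-attention variants.
* All beats must share one length and framing; there is no masking for
  variable-length batches.
* Mini-batch `R₁`/`R₂` are a stochastic approximation of their full-set
  definitions (switchable, at cost).
* The expert-editing API models the programmatic side of human-in-the-loop
  refinement only; recruiting, pairing and adjudicating human experts is
  out of scope.
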