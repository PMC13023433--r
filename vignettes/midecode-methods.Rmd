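---
title: "Decoding motor imagery from EEG: models and methods in midecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG: models and methods in midecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement — attenuates the
band-limited mu (8–13 Hz) and beta (14–30 Hz) sensorimotor rhythms over the
cortical representation of the imagined effector. This event-related
desynchronization (ERD) is lateralized: imagining the left hand attenuates
rhythms over the right motor cortex and vice versa, while foot and tongue
imagery engage midline and fronto-central sources. A brain–computer
interface (BCI) decodes these patterns from epoched multi-channel EEG trials
(channels × samples at a fixed rate) into one of four classes: left hand,
right hand, feet, tongue.

Three properties make the problem hard: low signal-to-noise ratio (the
rhythms sit on top of spatially correlated 1/f background activity),
non-stationarity within and across sessions, and strong inter-subject
variability (individual rhythm peak frequencies, topographies, and ERD
depths differ), which is why models trained on one cohort transfer poorly to
a new user.

## The model

`midecode` implements a hierarchical three-stage network that mirrors the
multi-scale structure of MI-EEG. For a trial $X \in \mathbb{R}^{C \times T}$
(defaults $C = 22$ channels, $T = 1000$ samples = 4 s at 250 Hz):

1. **Spatial–spectral encoder.** Four 1-D convolutional blocks
   (convolution → normalization → ReLU → max-pool). Kernels of length 5
   (20 ms) act along time over all channels; channel widths grow
   22 → 32 → 64 → 128 → 128. Convolutions are stride-1 with
   length-preserving (half-kernel) padding; all temporal reduction comes
   from the pooling stage, which floor-divides the length by 2 per block,
   so $T' = \lfloor\lfloor\lfloor\lfloor T/2\rfloor/2\rfloor/2\rfloor/2\rfloor$
   (62 for the defaults). Output: $H_{\mathrm{CNN}} \in \mathbb{R}^{D \times T'}$
   with $D = 128$.
2. **Temporal encoder.** A two-layer bidirectional LSTM with $d_h = 128$
   hidden units per direction; the output at each step concatenates the
   forward and backward states, $h_t = [\vec h_t; \overleftarrow h_t] \in
   \mathbb{R}^{2d_h}$, capturing how the ERD envelope evolves over the
   trial.
3. **Patch-tokenized Transformer.** The sequence is cut into
   $N = \lfloor (T' - p)/s \rfloor + 1$ overlapping patches of length
   $p = 24$ with stride $s = 12$ (50 % overlap; $N = 4$ at the defaults).
   Each patch is flattened time-major, projected affinely to $d = 128$
   dimensions, layer-normalized, and summed with non-learned sinusoidal
   positional encodings. Two post-norm Transformer encoder layers with 4
   heads ($d_k = d/h$, softmax scale $1/\sqrt{d_k}$), GELU feed-forward of
   width $2d$, and residual connections follow; a final layer norm and mean
   pooling over tokens yield a fixed-length embedding, classified by a
   two-layer head ($d \to d \to 4$) with softmax.

Component-wise the default architecture has 137,696 (conv) + 659,456
(BiLSTM) + 786,816 (patch embedding) + 265,216 (Transformer) + 17,028 (head)
= 1,866,212 trainable parameters; `count_parameters()` reproduces these
closed-form counts and the test suite verifies them against the actually
materialized arrays. Counting conventions that matter: recurrent gate blocks
carry two bias vectors each (input-side and hidden-side), the tokenizer has
one layer norm, each Transformer layer two plus one final, and the
feed-forward width is $2d$, not the more common $4d$. `estimate_macs()`
counts multiply–accumulates (multiplies only — norms, activations and
softmax excluded) and lands at ≈ 0.074 GMAC per trial for the defaults;
it serves as the deterministic latency surrogate for architecture search.

### Numerical choices

- **Batch normalization is the standard running-moment variant**: training
  normalizes by the current batch statistics (per channel over time ×
  batch) and maintains exponential-moving-average moments (momentum 0.1);
  inference normalizes by the frozen moments, so predicting a trial alone
  or inside any batch gives identical posteriors. The cross-trial sharing
  of normalization constants matters scientifically: the class signal is
  *which channels carry less band energy than usual*, and normalizing each
  trial by its own statistics (instance normalization) would erase exactly
  that contrast — measured directly as a collapse of desk-scale decoding
  to chance when instance statistics were tried. The running moments are
  non-trainable state carried alongside the parameters and excluded from
  the optimizer and the flat parameter vector.
- Max-pooling uses floor division (a trailing odd sample is dropped) and
  first-wins tie-breaking.
- Patch flattening is time-major (time index fastest) — arbitrary but
  fixed, so parameter layouts are reproducible.
- GELU is the exact ($\Phi$-based) form; its derivative is used in
  backpropagation, which is hand-written and verified against central
  finite differences to ~1e-7 relative error in the test suite.
- The head applies a GELU between its two affine maps (recorded as a config
  flag; the parameter count is unaffected).
- All initialization is Glorot-uniform (LSTM: uniform $\pm 1/\sqrt{d_h}$
  with forget-gate biases at 1) and deterministic in a single integer seed.

## Training regimen

`train_config()` defaults to AdamW (decoupled weight decay $10^{-2}$),
learning rate $3 \times 10^{-4}$ with a 10-epoch linear warm-up, halving on
validation plateau (after patience/2 non-improving epochs), batch size 32,
at most 100 epochs, early stopping after 10 consecutive non-improving
validation epochs (validation *loss* is monitored rather than accuracy —
the steadier signal at small n),
gradient-norm clipping at 1.0, and restoration of the best-validation
checkpoint.

## Evaluation protocols

- **Within-subject**: per subject, a stratified disjoint 50/50 split
  (emulating train/test sessions; the synthetic cohorts have no session
  structure, so the ratio is a config choice), validation carved from the
  training half.
- **LOSO** (leave-one-subject-out): the held-out subject contributes no
  trials to training or validation; validation is carved from training
  subjects only.
- **Subject-specific fine-tuning**: LOSO pretraining, then adaptation on a
  small labeled support set of the held-out subject (default 10 trials per
  class) and evaluation on that subject's remaining trials; pre- and
  post-adaptation metrics are both reported. With zero shots the protocol
  reduces exactly to LOSO (seeds are shared by construction).

Every protocol audits train/validation/test disjointness
(`audit_disjoint()`), reports accuracy and macro-F1 (unweighted mean of
per-class F1, with the 0-convention for empty classes), and derives all
randomness from one seed via `derive_seed()` (stage-named hashing, so adding
a pipeline stage never shifts another stage's stream). Subject-wise score
distributions are compared with a paired two-sided t-test, a two-sided
Wilcoxon signed-rank test ($W = \min(W^+, W^-)$, zero differences dropped,
exact enumeration for $n \le 12$, normal approximation with continuity
correction above), and Cohen's d with pooled SD.

## Meta-learning (MAML)

Each subject is a task with a small support set and a query set. From a
shared initialization $\theta$, the inner loop takes $k$ full-batch gradient
steps on the support loss, $\theta' = \theta - \alpha \nabla_\theta
L^{\mathrm{support}}(\theta)$ iterated; the outer loop updates $\theta
\leftarrow \theta - \beta \nabla_\theta \sum_i L_i^{\mathrm{query}}
(\theta_i')$. Defaults: $\alpha = 0.01$, $\beta = 0.001$, 5 inner steps,
meta-batches of 4 tasks, a 20-epoch supervised warm start before the
episodic phase (switch-over, not interleaved — the simpler of the two
unstated options), support sizes 5/10/15/20 per class, deployment analyzed
at 5/10/20 steps.

The second-order path (default) differentiates through the inner trajectory:
the meta-gradient is obtained by multiplying the query gradient by
$(I - \alpha H_k)$ at each inner step in reverse. The Hessian-vector
products are computed by central finite differences on the gradient
($Hv \approx [\nabla L(\theta + \epsilon v) - \nabla L(\theta - \epsilon
v)]/2\epsilon$ with $\epsilon$ scaled to $\|\theta\|/\|v\|$) — exact for
quadratics, which is what the closed-form unit tests exploit, and accurate
to the step size otherwise. A first-order switch stops gradients at
$\theta'$ for speed; the two agree in the $\alpha \to 0$ limit (verified as
a property test). Dropout is disabled inside the meta objective so
adaptation is deterministic. The engine is generic over an objective (flat
parameter vector + loss/gradient), so the identical code path runs both the
full network and the analytic toy problems.

By default `inner_adapt()` and `meta_step()` perform the exact unclipped
updates of the equations above. When the engine drives the network
(`meta_train()`, `few_shot_evaluate()`, the fine-tuning protocol), the
training regimen's gradient-norm clip (1.0) is applied to each inner step
and to the summed outer gradient: raw cross-entropy gradients of the
network routinely exceed norm 1, and unclipped 5-step adaptation at
$\alpha = 0.01$ can walk a well-trained model to chance. At desk-scale
episode budgets (tens of episodes rather than thousands) the outer rate is
rescaled to $\beta = 0.01$, mirroring the 10× learning-rate rescaling of
the compact supervised regimen; with the reference $\beta = 0.001$ and
clipped gradients, twenty episodes move the parameters by at most 0.02 —
indistinguishable from no meta-training.

## Architecture search (NSGA-II)

The search space is discrete: $d_h \in \{64,128,256\}$, $L \in \{1,2,3\}$,
$h \in \{2,4,6\}$, $p \in \{16,20,24\}$ with $s = p/2$, $d \in
\{64,128,256\}$ — $3^5 = 243$ raw combinations. Candidates with $d$ not
divisible by $h$ are repaired by resampling $h$; since no candidate $d$ is
divisible by 6, the reachable space has 162 members, all enumerable, which
the tests exploit as a global oracle. Three objectives are minimized:
error (1 − accuracy from short proxy training on 80 % of subjects), the MAC
latency surrogate, and the exact parameter count. The scalar fitness
$0.6\,\mathrm{err} + 0.3\,\mathrm{lat}_{\mathrm{norm}} +
0.1\,\mathrm{par}_{\mathrm{norm}}$ (min–max normalized over the search-space
bounds, which are computed in closed form) is used for logging and
tie-breaks only; survival follows NSGA-II fast non-dominated sorting plus
crowding distance, with binary tournament selection, uniform crossover
(probability 0.8), and per-gene mutation (probability 0.2).

One deviation from the textbook loop: the merged parent+child population is
**deduplicated by genome before survival**, refilling with fresh samples
when needed. In a 162-point space the population otherwise fills with
duplicate copies of converged genomes whose zero crowding distances can
evict unique Pareto members that had already been found. With
deduplication, a population of 20 recovers the exhaustive Pareto front of
the analytic test landscape within 10 generations. Every genome is
evaluated at most once per search (a cache keyed by genome), and the whole
search is deterministic in its seed.

## The synthetic generator

`generate_dataset()` emulates the *structure* of the standard four-class
benchmarks: 22 channels in a 10–20-style motor montage, 250 Hz, 4-s trials
whose first 0.5 s is pre-cue rest, balanced classes, multiple subjects.
Four source groups (left-central, right-central, midline-central,
fronto-central) project band-limited mu + beta rhythms through
unit-normalized topographies; during the post-cue interval the
class-targeted source's amplitude is multiplied by $(1 -
\mathrm{erd\_depth})$ with the fixed contralateral assignment (left hand →
right-central source, right hand → left-central, feet → midline, tongue →
fronto-central). Spatially correlated $1/f$ noise (fitted spectral slope
within ±0.2 of the configured exponent) is added at the configured SNR
(default 0 dB).

Inter-subject variability has three components: multiplicative rhythm gain
(SD 0.15), additive topography jitter (SD 0.1, re-normalized), and —
decisive for cross-subject transfer — individual rhythm peak frequencies
(mu peak ~ N(10.5, 1.2) Hz, beta peak ~ N(22, 2.5) Hz, bands clipped inside
the configured ranges), the standard physiological account of why decoders
degrade on unseen subjects. Everything is deterministic in
(`master_seed`, subject index, trial index).

What the generator does **not** model: ocular or muscle artifacts (the
artifact-rejection operators are exercised on constructed fixtures
instead), inter-session non-stationarity, volume-conduction forward models,
or realistic electrode noise spectra. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that the
architecture can learn lateralized band-power structure — not that
real-data benchmark accuracies would be reproduced.

Because the post-cue rhythm amplitude is multiplied by $(1 - e)$, post/pre
band-power ratios at targeted channels concentrate near $(1 - e)^2$ in the
noise-free limit; `erd_ratio()` pools power across trials before taking the
ratio (per-trial ratios on a 0.5-s pre-cue window are biased upward by the
small effective degrees of freedom of narrowband variance estimates).

## Preprocessing chain

Zero-phase (forward–backward) Butterworth filters via the `signal` package:
4–40 Hz band-pass of order 4, optional 50 Hz band-stop notch. FFT-domain
resampling to `round(n · target/rate)` samples. Cue-locked epoching with
baseline correction (pre-cue mean when the window starts before the cue,
whole-trial mean otherwise — the latter rule is a recorded config choice
for windows starting at the cue). Artifact rejection: amplitude (strict
`>` at ±100 µV, applied after filtering, as ordered in the pipeline) and a
joint-probability criterion made concrete as: per-channel empirical
densities from all trials pooled (histogram, Freedman–Diaconis bins),
per-trial statistic $-\overline{\log \hat p}$, single-pass rejection above
mean + 3 SD. Per-trial per-channel z-scoring (idempotent; zero-variance
channels raise an error naming trial and channel). No operation mutates its
input; provenance strings accumulate on the recording. Infomax-ICA ocular
removal is intentionally out of scope — the generator produces no ocular
artifacts and the chain leaves a natural insertion point before rejection.

## Desk-scale problem sizes

The full default architecture trains in minutes per epoch on one CPU, so
protocol-level experiments and the test suite use deliberately reduced
sizes, chosen once as representative rather than minimal:

- `compact_model_config()`: conv widths 8/12/16/16, $d_h = 16$, $d = 32$,
  $L = 1$, 2 heads, dropout halved — ≈ 49k parameters with every structural
  element of the full model intact; `compact_train_config()`: lr 3e-3,
  3-epoch warm-up, batch 4, a fixed 30-epoch budget with best-validation
  checkpointing (early stopping disabled: a 15-trial validation set is too
  noisy to stop on), and training-time augmentation — additive Gaussian
  noise (SD 0.2 of the standardized signal) and circular time shifts up to
  0.2 s, the standard small-cohort remedies in EEG decoding. Augmentation
  touches training batches only, never validation or test data.
- End-to-end protocol checks: 3 subjects × 40 trials/class at ERD depth
  0.6; meta-learning: 8 subjects × 12 trials/class at the default ERD depth
  0.4 with 5-shot support sets and a further-reduced architecture. The
  meta-learning comparison trains one supervised model on the pooled
  subjects (the jointly trained baseline), continues it with the episodic
  phase (the meta-trained initialization), and adapts both identically
  before scoring the query sets.
- Finite-difference gradient checks and MAML algebra run on toy
  configurations (3 channels, 48 samples) and scalar quadratics with
  closed-form oracles.

## Known limitations

- No GPU path; the hand-written BLAS-backed network is practical at compact
  scale but the full 1.87M-parameter model is for architecture accounting
  and single-trial inference, not large-scale training.
- Second-order MAML uses finite-difference HVPs: two extra gradient
  evaluations per inner step per task, with step-size-limited accuracy on
  non-quadratic losses.
- The joint-probability rejection statistic is one concrete realization of
  a criterion that has several in the literature; its rejection rates on
  real recordings will differ from EEGLAB's implementation in detail.
- `read_edf()` covers uniform-rate, 16-bit EDF; EDF+ annotations beyond
  channel labels and GDF event tables are not parsed.
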