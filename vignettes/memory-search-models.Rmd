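---
title: "Modelling memory search: CMR and a recurrent encoder-decoder with attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling memory search: CMR and a recurrent encoder-decoder with attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsearch)
```

## The task and the two models

In the free recall task a participant studies a list of `L` items drawn from
a pool of `N` words and then recalls as many as possible, in any order.
Behaviour in this task is remarkably structured: recall quality depends on
study position (primacy and recency in the serial position curve), recall
tends to start near the end of the list (probability of first recall), and
successive recalls come from nearby study positions, with a forward bias
(the lag conditional response probability, lag-CRP). `memsearch` implements
two models of the search process that produces this structure, plus the
machinery to fit, train, and compare them.

### The Context Maintenance and Retrieval model

CMR maintains a unit-norm context vector `c` in the item space `R^N`. When
the item at position `i` is studied, Hebbian outer products bind the
*pre-item* context `c_{i-1}` to the item's one-hot identity `f_i` in a pair
of association matrices (item-to-context and its transpose), and the context
then drifts toward the item's pre-experimental context:

    c_i = rho * c_{i-1} + beta * x_i,     x_i = f_i

with `rho = sqrt(1 + beta^2((c.x)^2 - 1)) - beta (c.x)` the unique
non-negative scalar that keeps `c` on the unit sphere. At recall, the
probability of retrieving the item studied at position `i` is a softmax with
inverse temperature `k` over the similarities `c_{i-1} . c_j` between the
current context and each studied item's stored pre-item context; unstudied
items have probability exactly zero. Retrieving an item reinstates a mixture
of its pre-experimental context and its stored experimental context,
weighted by `gamma_fc`, and the context drifts toward that mixture with rate
`beta_rec`. This reinstatement is the model's "jump back in time": it is
what makes neighbours of the just-recalled item likely next recalls, i.e.
the contiguity effect.

The free parameters and their roles:

| parameter  | range   | role                                                    | default |
|------------|---------|---------------------------------------------------------|---------|
| `beta_enc` | [0, 1]  | context drift rate at encoding                          | 0.7     |
| `beta_rec` | [0, 1]  | context drift rate at recall                            | 0.6     |
| `gamma_fc` | [0, 1]  | experimental vs pre-experimental reinstatement mix      | 0.5     |
| `k`        | >= 0    | retrieval inverse temperature (higher = less noisy)     | 8       |

The defaults are a mid-range regime in which simulated recall shows clear
contiguity and graded noise; they are the ground-truth values used for the
package's parameter-recovery experiments and were chosen once, from the
typical ranges used in context-model simulations, before any fitting.

### The sequence-to-sequence model

The second model is a GRU encoder-decoder. The encoder consumes the study
list item by item, and all hidden states `h_1..h_L` are stored in a trace
`H`. Decoding starts from `h_L`; at each output step the decoder state is
updated from the embedding of the previous output, dot-product attention
forms a context vector `alpha_j = sum_i softmax_i(h_j . h_i) h_i` over the
trace, and a tanh mixing layer combines `[h_j; alpha_j]` into a retrieval
state `hhat_j`. The output distribution scores each *studied* item by
`hhat_j . h_i` — the match between the current retrieval state and the
item's study-time state, which is the same form as CMR's retrieval rule —
plus a learned end-of-sequence logit.

The bridge between the models is exact: if the encoder trace rows are taken
to be CMR's stored pre-item contexts and the probe is `k * c`, the attention
context vector equals the expectation of CMR's reinstated context under the
recall softmax. `attention_equivalence_check()` verifies this identity
numerically:

```{r}
st <- encode_list(cmr_params(beta_enc = 0.6), c(3, 1, 4, 7), N = 10)
attention_equivalence_check(st, k = 1)
```

Because attention is the network's context-reinstatement mechanism, ablating
it (`attention = FALSE`, where the mixing layer sees only the decoder state)
is the model analogue of the loss of context reinstatement described in
medial-temporal-lobe amnesia. In the full-vocabulary output mode the
ablation removes *all* access to the stored encoder states — both the
attention context and the retrieval rule's study-context match — so the
ablated model must generate recalls from its recurrent state (working
memory) alone, through output embeddings. We adopted this after finding
that an ablation which keeps the retrieval rule's direct read of encoder
states shows no recall deficit whatsoever at small hidden dimensions: that
read is itself an episodic query, functionally interchangeable with
attention, and leaving it in place ablates nothing. In the in-list output
mode, where the studied positions are the only addressable outcomes, the
encoder-state scores are retained regardless of the attention flag.

## Design decisions in the open parts of the models

Several points are deliberately under-determined by the mathematical
formulation of the models; this section records the choices this package
makes and why.

**The normalizing scalar rho.** Only the constraint `||c|| = 1` is given.
We use the closed-form non-negative root above (the standard choice in
temporal-context models), applied after normalizing the drift input, for
both the encoding and recall updates.

**Initial context.** All algebra stays in `R^N`: the initial context is the
pre-experimental context (one-hot) of a reserved start slot — the first pool
item that is not on the current list — so it is orthogonal to every studied
item's context. When the whole pool is studied, the uniform unit vector is
used instead.

**CMR recall termination.** The recall phase stops after `max_attempts`
samples (default `L`) or as soon as the same item is sampled twice in a row
(both samples are recorded; the metrics module filters repeats). This is a
bounded, simple rule; the behavioural curves computed from the simulations
are insensitive to the exact bound because repeats and intrusions are
excluded from transition counting anyway.

**Retrieval rule of the network.** In `"in_list"` mode the softmax runs
over the `L` studied items plus end-of-sequence, so unstudied items have
exactly zero mass. Reinforcement learning and verbatim supervised targets
both require incorrect recalls to be expressible, so `"full_vocab"` mode
scores every item: studied items by the match to their stored encoder state
(keeping the CMR-aligned rule), unstudied items against learned output
embeddings, all in one softmax with the end-of-sequence logit. A score
temperature is exposed (default 1).

**Embeddings.** Learned embeddings are the default for task-optimized
models; `"random"` (fixed unit-norm rows) and `"pretrained"` (fixed rows
from the word pool, e.g. loaded with `load_word_vectors()`) keep the model
self-contained when no vector file is available. Start/end-of-sequence
markers always have learned rows outside the `N` item slots.

**End-of-sequence initialization.** The end-of-sequence bias is initialized
strongly negative (`-8`) rather than near zero. With a near-zero
initialization the early policy's recalls are mostly intrusions (at `N = 50`
and `L = 8`, about 84% of random emissions score -1), so terminating
immediately dominates every alternative and policy-gradient training
collapses into the silent policy before it can learn to discriminate studied
from unstudied items; we verified this collapse empirically at several
initializations. Starting with termination improbable is an optimistic
initialization: the agent first learns *what* to recall (which happens
within a few hundred updates) and only later learns *when* to stop, which
mirrors the intended course of learning rather than a degenerate shortcut.
The initialization is a property of `build_model()` only; nothing prevents
the trained policy from raising the logit through its learned projection.

## Fitting

### Supervised individual fitting

`train_supervised()` fits the network to a participant's literal recall
sequences (intrusions and repeats kept verbatim, terminated by the
end-of-sequence token) by teacher-forced cross-entropy, Adam (learning rate
0.001, moments 0.9/0.999), mini-batches of 32 trials, and early stopping on
validation loss with patience 5; `split_trials()` produces the 90/5/5
train/validation/test partition at list granularity. The best-validation
parameters are returned together with the held-out test loss.

### CMR fitting

`fit_cmr()` searches `beta_enc`, `beta_rec`, `gamma_fc`, `k` by a
Gaussian-process expected-improvement optimizer (Latin-hypercube initial
design; squared-exponential kernel with marginal-likelihood lengthscale
selection; 300 objective evaluations by default). Each candidate simulates
600 recall sequences over the dataset's own study lists and the objective is
the sum of the min-max-scaled RMSEs of the three behavioural curves. Two
numerical choices matter in practice. First, every evaluation uses the same
simulation stream (common random numbers), which makes the objective a
deterministic function of the parameters; with independent streams the
optimizer reliably found parameter combinations that "beat" the truth by
fitting per-evaluation noise in the lag-CRP, and recovery errors tripled.
Second, the min-max scaling constants are taken over the current run's
evaluations, excluding degenerate candidates (whose undefined curves are
scored at the RMSE bound of 1), so each curve type contributes comparably
regardless of its natural scale. The retrieval noise is searched on
`[0, 20]`: similarities are bounded by 1, so `k` near 20 is already close
to greedy recall.

Parameter recovery on synthetic participants is reliable for `beta_enc`
(the encoding drift rate dominates the shape of all three curves), while
`beta_rec`, `gamma_fc`, and `k` trade off against one another along a soft
ridge; on unlucky data realizations the fit can land on a compensating
combination. Fits should be read accordingly: the drift rate is the
interpretable quantity, the rest are effective parameters.

## Reinforcement learning of recall behaviour

`train_rl()` poses free recall as an episodic task: each episode presents a
fresh random list, the policy recalls until it emits end-of-sequence or hits
the step cap (`L + 2`, a small margin over the list length, analogous to the
bounded retrieval attempts of the CMR simulation — a looser cap of `2L` lets
early training plateau in repeat-heavy rambling and slows the emergence of
ordered recall), and rewards are +1 per first correct recall, -1 per
intrusion, -0.5 per repeat. Training follows PPO with the clipped surrogate
(clip 0.2), entropy bonus 0.01, discount 0.99, and batches of 4 episodes.
Choices the algorithm statement leaves open:

- **Advantages** use generalized advantage estimation with `lambda = 0.95`
  (`lambda = 1` recovers plain discounted returns; the estimator is
  oracle-tested against an explicit backward recursion) and are
  standardized within each batch.
- **Update epochs.** We run 4 optimization epochs per batch. With a single
  epoch the importance ratio is identically 1 and the clip never binds;
  multiple epochs are what make the clipped objective meaningful, and they
  substantially improve sample efficiency at small batch sizes.
- **Optimizer.** Adam with learning rate 0.002 annealed linearly to a
  tenth of that over the run (a standard PPO schedule). The starting rate
  is higher than the supervised default because the scaled-down training
  runs used throughout the package budget a few thousand updates, and the
  policy has to traverse three qualitative stages within them —
  discriminate studied items, suppress repeats, and settle on an ordered
  sweep; the anneal consolidates whichever recall strategy has emerged.
  Much larger rates re-trigger the termination collapse (Adam rescales the
  vanishing end-of-sequence gradients to full step size), so the schedule
  is a compromise between the two failure modes.
- **Epochs and checkpoints.** One epoch is `checkpoint_interval` iterations
  (5,000 in the full-scale configuration). Epoch 0 is the untrained,
  freshly initialized model; each subsequent checkpoint stores parameters,
  optimizer state, and RNG state, so interrupted runs resume exactly.

`evaluate_policy()` rolls the policy out on fresh lists (10,000 in the
full-scale configuration) and reports the behavioural curves, the mean
episode reward, and the mean recall probability (recalled fraction of each
list).

### Scaled-down study conditions

The full-scale training regime (50,000 iterations, hidden dimension 128,
10,000-list evaluations, 13 seeds per condition) is far beyond a desk-sized
compute budget. The package's tests and the acceptance script therefore use
a scaled-down regime chosen once: pool `N = 50`, lists of `L = 8`, hidden
dimension 32, 5,000 iterations, evaluations on 1,000 lists, and 3 seeds (5
seed pairs for the ablation contrast at 3,000 iterations). Under these
conditions a trained policy exhibits the qualitative optimal-recall
signature — reward rising across epochs, first recalls concentrated at
serial position 1, and the +1 lag dominating the lag-CRP — and early
checkpoints show the recency-dominated initiation that disappears with
training. What these scaled runs demonstrate is the *direction* of the
learning dynamics, not the end state of the full-scale runs: with an order
of magnitude fewer updates the curves are noisier and termination is less
sharp than in the full regime. One full-regime phenomenon the scaled
budget does not reproduce is the late *decline* of backward transitions:
as the policy acquires contiguity, transitions at lags -1 and +1 rise
together, and the subsequent unlearning of the backward share continues
well past the scaled budget's end. Recall-initiation recency, by
contrast, is already lost within the first epochs, as in the full regime.

## The behavioural statistics

`behavioral_curves()` computes the three canonical curves. Conventions
(the standard ones in the free-recall literature, stated here because they
matter for comparability):

- **SPC**: fraction of trials in which each studied position is recalled at
  least once; repeats do not double-count.
- **PFR**: position of the first *correct* recall; the denominator is all
  trials, so the curve sums to the fraction of trials with any correct
  recall — this keeps depressed-recall comparisons (e.g. ablated models)
  meaningful.
- **Lag-CRP**: repeats and intrusions are removed before transitions are
  counted; at each transition the possible lags exclude already-recalled
  items; lags with zero opportunities are reported as missing (`NA`), never
  imputed as zero, and are skipped in RMSE computations.

`wilcoxon_signed_rank()` implements the signed-rank test with an exact
small-sample path (the full `2^n` sign-assignment distribution, computed by
convolution over ranks) and a large-sample normal path with no continuity
correction by default; zero differences are dropped with a warning (the
original prescription), and ties among absolute differences redirect to the
normal method. The exact/normal switch in `compare_paired_models()` is at
`n = 25`, mirroring common statistical software. `rank_biserial()` is the
matched-pairs form `(2W - T)/T`.

## The synthetic-data generators

`make_wordpool()`, `make_study_lists()`, and `simulate_mock_participants()`
make every pipeline stage testable without downloads. Mock participants
differ in ground-truth CMR parameters arranged on a documented grid (so
recovery experiments have known spacing), with lists of 16 items by default,
matching the shape of a standard immediate free-recall study. The generators
are pure functions of (spec, seed).

What the synthetic data do *not* emulate: word frequency or semantic
structure (embeddings are isotropic random vectors), encoding-task
manipulations, inter-list effects, and response-time structure. Passing
tests on synthetic data therefore demonstrate correctness of the machinery
and recoverability of parameters under the model's own assumptions — not
that the models fit any particular empirical population.

## Numerical notes and limitations

- Context normalization is exact to floating point; tests assert
  `||c|| = 1` within 1e-6 on random drift sequences.
- Softmaxes subtract the maximum score before exponentiation.
- All stochastic operations consume R's RNG, so a single `set.seed()` makes
  any pipeline reproducible; the compiled simulation and rollout paths draw
  from the same RNG stream in the same order as the pure-R reference
  implementations, and the two paths are parity-tested.
- The gradient code (GRU backpropagation through time, attention, mixing
  layer, retrieval scores, PPO and cross-entropy heads) is hand-written and
  verified against central finite differences at 1e-4 relative tolerance.
- Reinforcement-learning outcomes at small scale retain seed-to-seed
  variability; directional claims in the tests are therefore asserted over
  majorities of seeds, not individual runs.
- `fit_cmr()` assumes fixed list length and a single parameter set per
  dataset; fitting participants with distinct parameters requires splitting
  the dataset by participant first.
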