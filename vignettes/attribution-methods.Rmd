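---
title: "Attribution methods for chemical language models: design and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribution methods for chemical language models: design and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in `clmexplain`, the
modelling assumptions behind them, the default parameters and their
rationale, and the known limitations. Code chunks are illustrative and not
evaluated when the vignette is built.

## 1. The model under explanation

`clmexplain` studies attribution for transformer regressors over SMILES
strings. The encoder is a pre-layer-norm transformer implemented entirely
in base R with hand-written forward and backward passes:

\[
x \leftarrow x + \mathrm{MHSA}(\mathrm{LN}_1(x)), \qquad
x \leftarrow x + \mathrm{FFN}(\mathrm{LN}_2(x)).
\]

Writing the backward pass by hand is deliberate: the relevance method
needs the attention score matrices \(A^l_h\) **and** the gradients
\(\partial \hat y / \partial A^l_h\) of the *raw scalar prediction* (not
the loss), captured exactly, in one forward and one reverse pass. An
automatic-differentiation framework would also provide this, but none is
available in a plain R installation, and the manual implementation keeps
the captured quantities unambiguous. Correctness is enforced by
finite-difference gradient tests in the suite.

A special readout token `<R>` is prepended at position 1; its final-layer
representation is the molecule-level feature vector (the regression
analogue of a classification token). Average pooling is also implemented,
but backpropagated token attribution is only defined for readout pooling —
average pooling spreads the prediction gradient uniformly across tokens,
so `attribute_readout()` refuses such models and directs the caller to the
Shapley module, which is pooling-agnostic.

The desk-scale configuration (`desk_config()`: 2 layers, 4 heads,
dimension 64, feed-forward width 128) is small enough to train on one CPU
in minutes while still exhibiting the phenomena of interest. A
masked-reconstruction pretraining pass (`masked_reconstruction_pretrain()`,
mask fraction 0.15) stands in for large-corpus pretraining: it gives the
encoder non-trivial token representations before regression training, and
its masked-token accuracy is checked against a majority-token baseline.

## 2. Relevance propagation

For each layer, attention scores are multiplied elementwise by their
gradients, clipped to the positive part, and averaged over heads:

\[
\bar A^l = \mathbb{E}_h\!\left[(A^l_h \odot \nabla A^l_h)^+\right].
\]

Relevance starts at the identity and accumulates with a skip-connection
term:

\[
R^0 = I, \qquad R^l = R^{l-1} + \bar A^l R^{l-1}.
\]

The attribution of each input token is the readout row of \(R^L\) with
the readout self-entry removed; entries are non-negative by construction.
Two implementation decisions deserve emphasis:

* **No row normalization between layers.** The update rule is applied
  exactly as stated. Normalizing \(\bar A^l + I\) to row-stochastic form
  (as in attention-rollout variants) changes the result; we implement the
  stated rule and verify it against an independent explicit-loop oracle to
  1e-10.
* **Gradient source.** Gradients are taken of the prediction itself, so
  attributions explain the model output, not its error against a label.

```{r}
at <- attribute_readout(model, tokenize("CCO", vocab = vocab))
at$token_relevance   # one non-negative value per token after <R>
at$atom_relevance    # projected onto atoms via the token-to-atom map
```

## 3. Shapley token attribution

Tokens are players; a coalition's value is the model prediction with all
tokens *outside* the coalition replaced by `<MASK>`. Masking by
substitution (never deletion) keeps the sequence length and geometry
intact — deleting tokens from a SMILES string usually produces an invalid
molecule and a different-length input. `exact_shapley()` enumerates all
\(2^m\) coalitions (refused above `max_T = 10`); `sampled_shapley()` uses
the permutation estimator with antithetic pairing (each sampled
permutation is paired with its reverse) and memoizes coalition values, so
no prediction is ever computed twice. Efficiency
(\(\sum_i \phi_i = v(\text{full}) - v(\varnothing)\)) holds to numerical
precision on every run; symmetry and dummy axioms are tested on
constructed games. Shapley values are signed, unlike the clipped
relevance scores.

## 4. Fingerprint bit-to-atom attribution

The circular fingerprint is implemented from scratch because the
attribution requires each bit's *environments* — center atom, radius, and
constituent atom set — which off-the-shelf fingerprint implementations
available to R do not expose. Atom invariants (element, degree, charge,
aromaticity) are iteratively hashed with sorted neighbour lists up to
radius 2 and folded into `n_bits` by modulo, so distinct environments can
collide on one bit; every environment that sets a bit is recorded.

`attribute_weights_to_atoms()` maps a linear model's per-bit weights to
atoms: each on bit's weight is split equally across the environments that
set it, then equally across each environment's atoms. The equal split
across colliding environments is a design decision (only the per-atom
division is forced by the method; the collision rule is not), chosen
because it preserves conservation: the per-atom sums equal the summed
weight of the on bits to 1e-10, always.

Targets for the fingerprint baselines can be robust-scaled
(`robust_scale()`): median-centered and divided by the spread between the
10th and 90th percentiles (linear-interpolation quantiles), which is
insensitive to the long tails of solubility-like properties.

## 5. Latent-feature sign decomposition

The linear regression head is bias-free, with a pre-head layer
normalization whose gain is learnable and whose shift is fixed at zero.
The prediction is then *exactly*

\[
\hat y = \sum_i w_i z_i
\]

over post-normalization features \(z\). Each feature falls into one of
four classes by the signs of \((z_i, w_i)\): \((+,+)\) and \((-,-)\)
contribute positively, \((+,-)\) and \((-,+)\) negatively.
`masked_feature_attribution()` zeroes a chosen feature subset *after* the
normalization in both the forward and reverse passes, so the masked
prediction equals the summed contribution of the kept features and the
positive-class and negative-class predictions partition the full one to
1e-6 (in practice, machine precision). Masking before the normalization
would change the statistics of the remaining features and destroy the
identity; the post-normalization masking point is essential.

## 6. Synthetic molecules and the planted property

The generator is graph-first: it grows a random valence-respecting tree
over C, N, O and Cl, optionally closes one 5- or 6-membered ring, and
writes the SMILES itself, so every emitted string is valid by
construction (the parser still validates each as a final gate). The
planted property

\[
y^* = 1.0\,(\#N + \#O) - 0.3\,\#C
\]

gives attribution methods a known ground truth: electronegative atoms
should receive positive importance, carbon skeletons negative. Each
molecule receives replicate noisy measurements (`noise_sd = 0.15`, about
10% of the target's spread — enough to make the accurate-split filter
meaningful without drowning the signal); half the molecules get 2–4
replicates so the filter has material to act on.

What the generator emulates: valid strings, branching, rings, a
structure-determined property with replicate noise. What it does not:
aromaticity (generated molecules are aliphatic; the parser and fingerprint
support aromatic input regardless), stereochemistry, charged species, and
any real physicochemical relationship — the planted property is linear in
atom counts by design, which is what makes recovery checkable.

Three split strategies mirror common evaluation practice: `random`
(ceiling 10% test), `accurate` (test = every molecule with more than one
measurement and replicate s.d. at most 0.2 — a pure, order-independent
filter), and `scaffold` (whole ring-framework groups assigned to one
side, so no scaffold straddles train and test; frameworks are computed by
iterative degree-1 pruning and matched by a refinement-based graph hash).

## 7. Training defaults

| parameter | default | rationale |
|---|---|---|
| optimizer | AdamW, betas 0.9/0.999 | standard for transformer fine-tuning; decay decoupled from the gradient |
| learning rate | 3e-4 | conventional transformer fine-tuning magnitude; stable at desk scale |
| weight decay | 0.01, skipped for LN and biases | standard practice; decaying normalization gains hurts |
| loss | Huber, delta = 1 | robust to the replicate-noise tails while quadratic near zero |
| epochs | 30 | sufficient for the desk model to beat the mean baseline by ~7x |
| batch size | 48 | gradient averaging granularity; full determinism under the seed |

Frozen mode pools each molecule once through the fixed encoder and trains
only the head on cached features; the encoder weights remain
bit-identical (asserted by serialization comparison in the tests).

## 8. Numerical and interface conventions

* Vocabulary ids are 0-based (`<PAD>` 0, `<MASK>` 1, `<R>` 2, `<UNK>` 3)
  as is conventional for token vocabularies; atom and token *positions*
  are 1-based, following R. The token-to-atom map is explicit about this.
* Layer normalization uses population variance with epsilon 1e-5 inside
  the square root.
* All stochastic entry points take a `seed` and restore the caller's RNG
  state; identical seeds give bit-identical results.
* `propagate()` rejects negative aggregated-attention entries (tolerance
  −1e-12) rather than silently clipping: a negative entry means the
  positive-part contract upstream was violated.

## 9. Known limitations

* **Negative-class attribution is not near-zero at desk scale.** On the
  trained desk fixture, restricting attribution to negative-contribution
  features yields token relevance with an L1 norm around 45–55% of the
  unrestricted attribution's, not under 1%. The mechanism that would
  suppress it — positive-part clipping removing sign-flipped
  attention-gradient products — evidently requires representations in
  which negative-feature gradients flow through attention with flipped
  sign almost everywhere, which the 2-layer, 64-dimensional model trained
  here does not produce. The package measures and reports this ratio
  rather than asserting the near-zero behaviour; the corresponding
  acceptance test states the strict threshold and fails honestly.
* Exact Shapley is exponential in token count; the sampled estimator's
  error is reported per token and should be checked against the intended
  resolution.
* The hand-written SMILES parser covers the organic subset, bracket
  atoms, aromatic lowercase forms, ring closures (including `%nn`),
  branches and dot-separated fragments, with a valence screen on
  non-bracket atoms. It is not a full SMILES implementation (no
  stereochemistry, no isotopes beyond bracket storage, no canonical
  output).
* Desk-scale accuracy numbers are fixture-specific; they demonstrate the
  pipeline's behaviour, not state-of-the-art property prediction.
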