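---
title: "Meta-learning plasticity rules through fixed random feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learning plasticity rules through fixed random feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaplast)
```

## The problem

Backprop trains a layered network by transporting the output error backward
through feedback connections that are exact transposes of the forward
weights. Biologically, no mechanism is known that could keep two separate
synaptic pathways mirror-symmetric — the *weight transport problem*.
Feedback alignment replaces $W^T$ with fixed random feedback matrices $B$:
it works for shallow networks and plentiful data, but collapses when the
network is deep, the data stream is online (batch size one) and short. This
package implements a meta-learning framework that searches a space of
*local* synaptic plasticity rules for combinations that restore fast online
learning under fixed random feedback, and the diagnostics that make the
discovered rules interpretable.

## Model

A fully connected classifier without biases,

$$z_\ell = W_{\ell-1,\ell}\, y_{\ell-1}, \qquad y_\ell = \sigma(z_\ell),$$

with softplus hidden activations
$\sigma(z) = \tfrac{1}{\beta}\log(1 + e^{\beta z})$ (default $\beta = 10$;
smooth, hence twice differentiable, which the outer loop requires) and a
softmax output. The output teaching signal is the cross-entropy gradient
$e_L = y_L - \mathrm{onehot}(y)$; upstream signals are transported by

$$e_{\ell-1} = B_{\ell,\ell-1}\, e_\ell \odot \sigma'(z_{\ell-1}),$$

with $B$ read as $W^T$ in backprop ("BP") mode — a live view of the current
weights, not a copy — and held fixed and random in feedback-alignment
("FA") mode. An input-layer *synthetic error*
$e_0 = B_{1,0} e_1 \odot (1 - e^{-\beta y_0})$ supplies a pre-synaptic
error to first-layer plasticity terms; the factor equals
$\sigma'(z_0)$ expressed through the activation itself (the identity
$1 - e^{-\beta\,\sigma(z)} = \sigma'(z)$ holds exactly), and $e_0$ never
updates a parameter on its own.

### The plasticity rule pool

A candidate rule for the layer-$\ell$ weights is a linear combination
$\mathcal F(\Theta) = \sum_{r=0}^{9} \theta_r \mathcal F^r$ of ten local
terms built from $y_{\ell-1}, y_\ell, e_{\ell-1}, e_\ell$ and
$W_{\ell-1,\ell}$ (see `?plasticity_term` for the full list): the
pseudo-gradient term $-e_\ell y_{\ell-1}^T$, the error-Hebbian ("eHebb")
term $-e_\ell e_{\ell-1}^T$, weight decay, several higher-order
combinations, and Oja's rule
$y_\ell y_{\ell-1}^T - (y_\ell y_\ell^T) W_{\ell-1,\ell}$, which replaces
pure Hebbian growth (unstable) by Hebbian growth with an orthonormalizing
stabilizer. The coefficients $\Theta$ are *shared by all layers*, which is
what keeps a discovered rule interpretable as a rule rather than a lookup
table. Coefficients are unconstrained reals — and indeed meta-learning
consistently drives $\theta_2$ *negative* on our synthetic tasks, which is
the aligning direction given that the expected error outer product is
proportional to $+B^T$ (below).

Terms 0–4 are strictly local (the update to $W_{jk}$ depends only on the
$j$-th post-synaptic and $k$-th pre-synaptic signals and $W_{jk}$); terms
5–9 contain sums over the post-synaptic population. The package asserts
strict locality only for terms 0–4.

### The meta-learning loop

Each episode draws a fresh $M$-way task ($K$ training, $Q$ query items per
class), re-initializes $W$ and $B$ by uniform Glorot draws (weights are
never meta-learned — the rule must train a naive network), runs one online
epoch of $M \cdot K$ single-sample updates
$W \leftarrow W + \mathcal F(\Theta)$, and evaluates the meta-loss

$$\mathcal L_{\mathrm{meta}}(\Theta)
  = \mathcal L(f_W(X_{\mathrm{query}}), Y_{\mathrm{query}})
  + \lambda \lVert \Theta \rVert_1$$

on the query set. One ADAM step (rate $10^{-3}$, moments $0.9/0.999$,
$\epsilon = 10^{-8}$) is then taken on the active coefficients using the
exact gradient of the meta-loss through the whole unrolled inner loop.
The L1 penalty sparsifies the pool so that the surviving terms are few and
readable; its subgradient at zero is taken as zero. $\lambda = 0$ for
single-rule benchmarking; the package default for pool runs is
$\lambda = 10^{-3}$, exposed in the configuration because the right value
scales with the meta-gradient magnitudes of the task distribution (for the
reduced-scale tasks in our tests, $0.01$ is the calibrated equivalent).

### Exact meta-gradients by complex-step differentiation

No automatic-differentiation engine is used. Every operation in the
forward pass, error propagation and weight update is written closed under
complex arithmetic, and the derivative of the query loss with respect to
$\theta_r$ is obtained by re-running the inner loop at
$\theta_r + ih$ ($h = 10^{-20}$) and reading off
$\mathrm{Im}(\mathcal L)/h$. For analytic maps this is exact to machine
precision — there is no subtractive cancellation, so $h$ can sit far below
any noise floor. Numerical-stability branches (the shifted softplus and
softmax) test only real parts, so each branch stays analytic in a
neighborhood of the real axis. The cost is one extra inner-loop run per
active coefficient per episode (so a 10-term pool costs ~11 inner runs);
the unrolled loop is differentiated in full, with no truncation — memory
is not a constraint at these sizes because forward mode stores nothing.
The implementation is validated against central finite differences on
small unrolled loops (relative error $\sim 10^{-10}$, far inside the
$10^{-4}$ tolerance asserted in the tests).

An episode whose weights or losses become non-finite (possible early in a
pool run, when aggressive coefficient settings make activations blow up)
is recorded as aborted, the coefficient step is skipped, and the run
continues.

## Diagnostics

* **Alignment angles.** `layer_alignment()` propagates the same output
  error through both the FA and BP pathways of one forward pass and
  reports the angle between the signals at every layer,
  $\alpha_0 \dots \alpha_L$ in degrees ($\alpha_L = 0$ by construction;
  $\alpha_0$ is the synthetic-error angle). During meta-training, angles
  are computed on every inner-loop sample and averaged within the episode
  (the averaging population is a package choice; samples with a vanishing
  signal are excluded rather than imputed at 90°, which would bias early
  episodes). Summaries of the layer-assignment experiment additionally
  average episodes after a burn-in (default 100 of 500).
* **Orthonormality error.** `orthonormality_error()` measures proximity of
  a hidden layer to the stable fixed point $W W^T = I$ of Oja's rule via
  the reconstruction error
  $E_W = \lVert z_\ell - W \bar y_{\ell-1}\rVert_2^2$,
  $\bar y_{\ell-1} = W^T \sigma(z_\ell)$; the last layer is excluded from
  reports.
* **Feedback correlation.** In a linear network the expected outer product
  of consecutive teaching signals satisfies
  $\mathbb E[e_\ell e_{\ell-1}^T \mid B] \propto B^T$ — the mechanism by
  which the eHebb term pushes forward weights toward the feedback
  transposes and thereby aligns the pathways. `eq9_check()` verifies this
  by Monte-Carlo on identity-activation networks only; it is not asserted
  for nonlinear networks, which lie outside the statement's assumptions.
* **Principal-subspace recovery.** `train_oja_layer()` trains a single
  compression layer with the pure Oja term on Gaussian data of known
  covariance under an annealed step size $\mathrm{lr}_0/(1 + t/\tau)$ (the
  usual Robbins–Monro schedule; at a fixed step size the stochastic
  equilibrium leaves a residual subspace angle of several degrees). The
  row space converges to the top-$k$ eigenvector subspace and $E_W \to 0$.

## The synthetic task generator

The episodic experiments are defined over a 47-class pool of 784-pixel
images. The packaged generator emulates that statistical role without any
download: each class has a fixed prototype (dense Gaussian pattern around
mid-gray, or sparse bright "blob glyphs"), and samples are prototype plus
i.i.d. pixel noise, clipped to $[0,1]$. The defaults (47 classes, 784
dims, `prototype_scale = 0.3`, `noise_scale = 0.2`) were calibrated once
and frozen: a 784-170-130-100-70-47 network trained by plain online
backprop at $\theta_0 = 10^{-3}$ reaches ~50% mean query accuracy after
250 samples (chance is 1/47 over the 47-unit head, 0.2 against the 5
episode classes), and task difficulty is monotone in `noise_scale`.

What the generator does *not* emulate: stroke correlations, within-class
style variation, and class imbalance of handwritten-character data.
Passing tests on synthetic tasks therefore demonstrate the mechanics of
the framework (credit assignment, alignment, subspace extraction), not
performance claims about any real dataset; real IDX-format datasets drop
in through `idx_source()` unchanged.

## Problem sizes used by the test suite

The full protocol (5-way tasks, $K = 50$, $Q = 10$, 600 episodes, 20
trials, the 784-170-130-100-70-47 network) is what `experiment_preset()`
encodes. The packaged tests exercise the same code paths at reduced
problem sizes, chosen as the smallest where each qualitative effect is
statistically unambiguous across seeds: rule benchmarks use a
64-32-24-16-8 network, 5-way/K=10 episodes, 100 episodes and 5 seeds per
condition (backprop vs. baseline accuracy gap ≥ 0.2; eHebb lowers the
deepest hidden angle by 4–11°; Oja lowers mean $E_W$ 2.5–4× while moving
angles < 0.5°); the sparsification property uses a 36-24-16-8 network,
250 episodes and the $\lambda$ grid $\{0, 0.01, 0.1\}$; the
layer-assignment sweep uses 150 episodes with a 100-episode burn-in.

## Numerical and design choices

* Uniform Glorot initialization for both $W$ and $B$ (the variant is a
  free choice; normal draws would do as well).
* Softplus and softmax in shifted, overflow-safe forms; cross-entropy via
  log-sum-exp.
* The training stream is shuffled once per episode with the episode seed;
  trial seeds derive from the base seed by a fixed counter scheme
  (`base + 10007 * i`), so every run is exactly replayable.
* The last layer receives the full composite rule, including the Oja term
  (no detrimental effect; keeping the rule uniform preserves
  meta-parameter sharing).
* "Surviving" pool terms are counted as $|\theta_r| \ge 10\%$ of
  $\max_r |\theta_r|$ at the final episode — scale-free, so it is robust
  to the overall learning-rate magnitude.
* Checkpoints serialize to JSON at 17 significant digits, the smallest
  count that round-trips IEEE doubles exactly.

## Known limitations

* Forward-mode meta-gradients cost one inner re-run per active
  coefficient; for rule pools much larger than ten terms a reverse-mode
  tape would win.
* The sparsity pattern of a full-scale pool run depends on $\lambda$,
  which must be calibrated to the task distribution; the package exposes
  it rather than fixing it.
* Feedback matrices are plastic nowhere: discovering feedback plasticity
  rules is out of scope.
* Only fully connected, bias-free architectures are supported.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_task_spec(class_pool_size = 20, input_dim = 64)
source <- make_synthetic_source(spec, seed = 11)
net <- network_config(c(64, 32, 24, 16, 8), feedback_mode = "FA")
cfg <- meta_config(net, named_rule("eHebb"), source,
                   episodes = 100, M = 5, K = 10, Q = 4, trial_seed = 1)
fit <- meta_train(cfg)
tail(fit$history[, c("episode", "meta_accuracy", "theta_0", "theta_2",
                     "alpha_3")], 3)
```

The history records, per episode, the meta-loss and meta-accuracy, the
coefficient snapshot, the per-layer mean alignment angles and the
hidden-layer orthonormality errors — the same columns the command-line
interface streams to `history.csv`.
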