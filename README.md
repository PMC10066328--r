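# metaplast

Meta-learning of biologically plausible synaptic plasticity rules for deep
networks trained through **fixed random feedback pathways**.

## The problem

Backprop transports the output error of a layered network backward through
feedback connections that are exact transposes of the forward weights
(`e_{l-1} = W_l^T e_l ⊙ σ'(z_{l-1})`). Biology offers no mechanism that
keeps two synaptic pathways mirror-symmetric — the *weight transport
problem*. Feedback alignment replaces `W^T` with fixed random matrices `B`,
which works for shallow networks but fails for deep models trained online on
little data. `metaplast` is for computational neuroscientists and
learning-rule researchers who want to *discover* and *interpret* local
plasticity rules that close this gap.

## What it implements

* A bias-free fully connected classifier with softplus hidden layers
  (`σ(z) = log(1 + e^{βz})/β`, β = 10), softmax output, and either symmetric
  (`BP`) or fixed random (`FA`) feedback, including the synthetic
  input-layer error `e_0 = B_{1,0} e_1 ⊙ (1 − e^{−β y_0})`.
* A pool of ten local plasticity terms `F^0 … F^9` (pseudo-gradient,
  error-Hebbian `−e_l e_{l-1}^T`, weight decay, higher-order combinations,
  and Oja's rule `y_l y_{l-1}^T − (y_l y_l^T) W`), combined as
  `F(Θ) = Σ_r θ_r F^r` with one coefficient vector shared by all layers.
* The two-level learning scheme: per episode, a freshly initialized network
  is trained online (batch size 1, `M·K` samples) with `F(Θ)`, and the
  coefficients take one ADAM step on the L1-penalized meta-loss
  `L(f_W(X_query), Y_query) + λ‖Θ‖₁`, with **exact** gradients through the
  unrolled inner loop obtained by complex-step differentiation (no autodiff
  framework involved; validated against finite differences to ~1e-10).
* Diagnostics: per-layer alignment angles `α_l` between feedback-alignment
  and backprop teaching signals, the orthonormality error
  `E_W = ‖z_l − W W^T σ(z_l)‖²` of Oja's fixed point, a Monte-Carlo check of
  the linear-network correlation `E[e_l e_{l-1}^T] ∝ B^T`, and
  principal-subspace recovery for the Oja term.
* Episodic `M`-way task sampling from IDX-format image datasets (the
  MNIST-family container) or from a calibrated synthetic 47-class generator,
  so every experiment runs with no download; multi-trial orchestration with
  percentile-bootstrap confidence bands; a command line.

## A worked example

Meta-train the eHebb rule (pseudo-gradient + error-Hebbian term) on 5-way
synthetic episodes through fixed random feedback:

```r
library(metaplast)
spec   <- synthetic_task_spec(class_pool_size = 20, input_dim = 64)
source <- make_synthetic_source(spec, seed = 11)
net    <- network_config(c(64, 32, 24, 16, 8), feedback_mode = "FA")
cfg    <- meta_config(net, named_rule("eHebb"), source,
                      episodes = 100, M = 5, K = 10, Q = 4, trial_seed = 1)
fit <- meta_train(cfg)
fit
#> <meta_fit> 100 episodes (0 aborted)
#>   final meta-accuracy (last 10 episodes): 0.240
#>   theta: theta_0=0.03789 theta_2=-0.05099
round(tail(fit$history[, c("episode", "meta_accuracy", "theta_0",
                           "theta_2", "alpha_3")], 3), 4)
#>     episode meta_accuracy theta_0 theta_2 alpha_3
#> 98       98          0.50  0.0375 -0.0492 90.6195
#> 99       99          0.25  0.0376 -0.0498 78.3513
#> 100     100          0.10  0.0377 -0.0504 84.5191
```

The learning rate `theta_0` has grown from its 1e-3 initialization, and the
error-Hebbian coefficient `theta_2` has moved away from zero in the
direction that pushes forward weights toward the feedback transposes —
visible in `alpha_3`, the angle (degrees) between the deepest hidden
teaching signal and its backprop counterpart, dipping below the ~90° of
untrained random feedback. Accuracy per episode is quantized (here 20 query
points), so single episodes swing; `run_trials()` +
`aggregate_episodes()` produce the mean ± bootstrap-band curves used for
comparisons, and `experiment_preset()` carries the full-scale recipes
(784-170-130-100-70-47 network, K = 50, 600 episodes, 20 trials).

From a shell, the same run is:

```sh
inst/cli/metaplast meta-train --config config.yaml --out results/
inst/cli/metaplast benchmark --preset benchmark-fa --out results/fa/
inst/cli/metaplast simulate-data --spec spec.yaml --out data/
```

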