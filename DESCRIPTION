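Package: metaplast
Title: Meta-Learning of Biologically Plausible Synaptic Plasticity Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers interpretable synaptic plasticity rules that train deep
    fully connected networks through fixed random feedback pathways. Implements
    online inner-loop adaptation with a parameterized pool of ten local
    plasticity terms, outer-loop meta-optimization of the shared coefficients
    by ADAM on an L1-penalized meta-loss (with exact meta-gradients obtained by
    complex-step differentiation through the unrolled inner loop), and the
    diagnostics used to interpret discovered rules: alignment angles between
    feedback-alignment and backprop teaching signals, and the orthonormality
    error of hidden-layer weights under Oja's rule. Includes episodic M-way
    task samplers for IDX-format image datasets and a calibrated synthetic
    task generator, multi-trial orchestration with bootstrap confidence
    intervals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
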