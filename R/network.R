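# Fully connected network with separate forward (W) and feedback (B) pathways.

#' Network configuration
#'
#' Describes an L-layer fully connected classifier without biases. The first
#' element of `layer_sizes` is the input dimension, the last the number of
#' output units (one per class); hidden layers use the softplus activation
#' and the output layer uses softmax. Teaching signals are transported
#' backward either through the transposes of the forward weights
#' (`feedback_mode = "BP"`, i.e. backprop) or through fixed random feedback
#' matrices drawn independently of the forward weights
#' (`feedback_mode = "FA"`, feedback alignment).
#'
#' @param layer_sizes integer vector of length L+1 (L >= 2): input dimension,
#'   hidden sizes, class count.
#' @param beta softplus smoothness parameter (default 10).
#' @param feedback_mode `"FA"` for fixed random feedback, `"BP"` for
#'   symmetric (transposed) feedback.
#' @param activation hidden-layer activation: `"softplus"` (default) or
#'   `"identity"` (used for linear-network diagnostics).
#' @return an object of class `network_config`.
#' @examples
#' cfg <- network_config(c(784, 170, 130, 100, 70, 47))
#' @export
network_config <- function(layer_sizes, beta = 10,
                           feedback_mode = c("FA", "BP"),
                           activation = c("softplus", "identity")) {
  feedback_mode <- match.arg(feedback_mode)
  activation <- match.arg(activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3)
    stop("layer_sizes must describe at least 2 layers (length >= 3)")
  if (any(!is.finite(layer_sizes)) || any(layer_sizes < 1))
    stop("layer_sizes must be positive integers")
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("beta must be a positive scalar")
  structure(
    list(layer_sizes = layer_sizes, beta = beta,
         feedback_mode = feedback_mode, activation = activation),
    class = "network_config"
  )
}

# Xavier/Glorot uniform draw for an (nr x nc) matrix
.xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a network
#'
#' Draws forward weights `W` and feedback matrices `B` by Xavier (Glorot)
#' uniform initialization. The two pathways are drawn independently, so in
#' `"FA"` mode `B` is not related to the transpose of `W`. In `"BP"` mode the
#' stored `B` is ignored: every read of the feedback matrix returns the
#' transpose of the *current* forward weight, so symmetric feedback tracks
#' the evolving weights.
#'
#' @param config a [network_config()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an object of class `plasticity_network` with fields `config`,
#'   `W` (list of L matrices, `W[[l]]` of shape size_l x size_{l-1}) and
#'   `B` (list of L matrices, `B[[l]]` of shape size_{l-1} x size_l).
#' @export
init_network <- function(config, seed) {
  stopifnot(inherits(config, "network_config"))
  sz <- config$layer_sizes
  L <- length(sz) - 1
  .with_seed(seed, {
    W <- lapply(seq_len(L), function(l) .xavier(sz[l + 1], sz[l]))
    B <- lapply(seq_len(L), function(l) .xavier(sz[l], sz[l + 1]))
    structure(list(config = config, W = W, B = B),
              class = "plasticity_network")
  })
}

#' Read the feedback matrix of layer l
#'
#' In `"BP"` mode this is a dynamic view of `t(W[[l]])`; in `"FA"` mode it is
#' the stored fixed random matrix.
#'
#' @param state a `plasticity_network`.
#' @param l layer index in 1..L.
#' @return matrix of shape size_{l-1} x size_l.
#' @export
feedback_matrix <- function(state, l) {
  if (state$config$feedback_mode == "BP") t(state$W[[l]]) else state$B[[l]]
}

# hidden-layer activation / derivative dispatch
.act <- function(z, config) {
  if (config$activation == "identity") z else softplus(z, config$beta)
}
.act_grad <- function(z, config) {
  if (config$activation == "identity") z * 0 + 1 else softplus_grad(z, config$beta)
}

#' Forward pass
#'
#' Computes `z_l = W_l y_{l-1}` and `y_l = sigma(z_l)` for every layer;
#' the final layer applies softmax so `y_L` is a probability vector.
#'
#' @param state a `plasticity_network`.
#' @param x input vector of length equal to the input dimension.
#' @return an object of class `forward_trace` with fields `y0` (the input),
#'   `z` (list of L pre-activation vectors) and `y` (list of L activations).
#' @export
forward <- function(state, x) {
  cfg <- state$config
  sz <- cfg$layer_sizes
  x <- as.vector(x)
  if (length(x) != sz[1])
    stop(sprintf("input length %d does not match input dimension %d",
                 length(x), sz[1]))
  L <- length(state$W)
  z <- vector("list", L)
  y <- vector("list", L)
  prev <- x
  for (l in seq_len(L)) {
    z[[l]] <- as.vector(state$W[[l]] %*% prev)
    y[[l]] <- if (l == L) .softmax(z[[l]]) else .act(z[[l]], cfg)
    prev <- y[[l]]
  }
  structure(list(y0 = x, z = z, y = y), class = "forward_trace")
}

#' Output-layer teaching signal
#'
#' For softmax output with cross-entropy loss the gradient of the loss with
#' respect to the output pre-activation is `e_L = y_L - onehot(label)`.
#'
#' @param trace a `forward_trace`.
#' @param label class index in 1..n_class.
#' @return the error vector `e_L`.
#' @export
output_error <- function(trace, label) {
  yL <- trace$y[[length(trace$y)]]
  n <- length(yL)
  if (!is.numeric(label) || length(label) != 1 || label < 1 || label > n ||
      label != round(label))
    stop(sprintf("label must be an integer in 1..%d", n))
  e <- yL
  e[label] <- e[label] - 1
  e
}

#' Backward error propagation
#'
#' Transports the output teaching signal upstream through the feedback
#' pathway: `e_{l-1} = (B_l e_l) * sigma'(z_{l-1})` for l = L..2. The
#' input-layer ("synthetic") error is defined by expressing the softplus
#' derivative through the activation itself,
#' `e_0 = (B_1 e_1) * (1 - exp(-beta * y_0))`, which equals
#' `(B_1 e_1) * sigma'(z_0)` whenever `y_0` is a softplus image. `e_0` exists
#' only to supply a pre-synaptic error to first-layer plasticity terms; it
#' never updates a parameter by itself. In `"BP"` mode the feedback matrices
#' are read as the transposes of the current forward weights, so the trace
#' equals the exact loss gradient with respect to every `z_l`.
#'
#' @param state a `plasticity_network`.
#' @param trace the `forward_trace` of the same input.
#' @param e_L output error from [output_error()].
#' @return an object of class `error_trace`: a list `e` of L+1 vectors where
#'   `e[[l + 1]]` holds the layer-l signal `e_l` (so `e[[1]]` is `e_0`).
#' @export
propagate_errors <- function(state, trace, e_L) {
  cfg <- state$config
  L <- length(state$W)
  e <- vector("list", L + 1)
  e[[L + 1]] <- as.vector(e_L)
  for (l in seq(L, 2)) {
    e[[l]] <- as.vector(feedback_matrix(state, l) %*% e[[l + 1]]) *
      .act_grad(trace$z[[l - 1]], cfg)
  }
  back <- as.vector(feedback_matrix(state, 1) %*% e[[2]])
  e[[1]] <- if (cfg$activation == "identity") back
            else back * (1 - exp(-cfg$beta * trace$y0))
  structure(list(e = e), class = "error_trace")
}

#' Cross-entropy loss of a trace
#'
#' `-log y_L[label]`, evaluated in the log-sum-exp form
#' `logsumexp(z_L) - z_L[label]` for numerical stability.
#'
#' @inheritParams output_error
#' @return scalar loss.
#' @export
cross_entropy <- function(trace, label) {
  zL <- trace$z[[length(trace$z)]]
  .logsumexp(zL) - zL[label]
}

#' @export
print.plasticity_network <- function(x, ...) {
  sz <- x$config$layer_sizes
  cat(sprintf("<plasticity_network> %s | feedback %s | activation %s\n",
              paste(sz, collapse = "-"), x$config$feedback_mode,
              x$config$activation))
  invisible(x)
}

#' Write a network state to disk
#'
#' Serializes the configuration and every matrix (named `W_1 ... W_L`,
#' `B_1 ... B_L`) to a portable JSON container at full double precision, so
#' that [read_network_state()] reproduces the state exactly.
#'
#' @param state a `plasticity_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_state <- function(state, path) {
  L <- length(state$W)
  obj <- list(
    layer_sizes = state$config$layer_sizes,
    beta = state$config$beta,
    feedback_mode = state$config$feedback_mode,
    activation = state$config$activation,
    W = stats::setNames(state$W, paste0("W_", seq_len(L))),
    B = stats::setNames(state$B, paste0("B_", seq_len(L)))
  )
  # I(17) = 17 significant digits: the smallest count that round-trips
  # IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a network state written by [write_network_state()]
#'
#' @param path file path.
#' @return a `plasticity_network`.
#' @export
read_network_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- network_config(obj$layer_sizes, beta = obj$beta,
                        feedback_mode = obj$feedback_mode,
                        activation = obj$activation)
  state <- list(config = cfg,
                W = unname(obj$W),
                B = unname(obj$B))
  structure(state, class = "plasticity_network")
}
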