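# Interpretability instruments: alignment angles between feedback-alignment
# and backprop teaching signals, the orthonormality error of hidden weights,
# the linear-network feedback-correlation check, and helpers for analysing
# the Oja term as an online principal-subspace extractor.

#' Angle between two signals, in degrees
#'
#' `acos` of the cosine similarity. If either vector's norm is below `tol`
#' the angle is undefined and `NA` is returned; callers exclude such samples
#' from averages (rather than imputing 90 degrees, which would bias
#' early-training summaries).
#'
#' @param u,v numeric vectors of equal length.
#' @param tol norm threshold below which the angle is undefined.
#' @return angle in \[0, 180\] degrees, or `NA`.
#' @export
alignment_angle <- function(u, v, tol = 1e-12) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < tol || nv < tol) return(NA_real_)
  c_ <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Per-layer alignment of feedback-alignment signals with backprop
#'
#' From one forward pass and its output error, propagates the error twice --
#' once through the state's feedback matrices and once through the
#' transposes of the current forward weights -- and reports the angle
#' between the two signals at every layer, `alpha_0 ... alpha_L`.
#' `alpha_L = 0` always, since both pathways share `e_L`; for a BP-mode
#' state every angle is zero.
#'
#' @param state a `plasticity_network`.
#' @param trace the `forward_trace` of an input.
#' @param label the class label used for the output error.
#' @return named numeric vector `alpha_0 ... alpha_L` (degrees).
#' @export
layer_alignment <- function(state, trace, label) {
  L <- length(state$W)
  eL <- output_error(trace, label)
  et <- propagate_errors(state, trace, eL)
  a <- .trace_angles(state, trace, et)
  stats::setNames(a, paste0("alpha_", 0:L))
}

#' Orthonormality error of one hidden layer
#'
#' Proximity of `W_l` to the stable fixed point of Oja's rule
#' (`W W^T = I`), measured through the reconstruction error
#' `E_W = || z_l - W_l ybar_{l-1} ||^2` with
#' `ybar_{l-1} = W_l^T sigma(z_l)`. Zero when the rows of `W_l` are
#' orthonormal and the activation is the identity. The last layer is
#' conventionally excluded from reports.
#'
#' @param state a `plasticity_network`.
#' @param trace a `forward_trace`.
#' @param layer layer index in 1..L.
#' @return nonnegative scalar.
#' @export
orthonormality_error <- function(state, trace, layer) {
  L <- length(state$W)
  stopifnot(layer >= 1, layer <= L)
  z <- trace$z[[layer]]
  sig_z <- if (layer == L) trace$y[[L]] else .act(z, state$config)
  ybar <- as.vector(t(state$W[[layer]]) %*% sig_z)
  resid <- z - as.vector(state$W[[layer]] %*% ybar)
  sum(Re(resid)^2)
}

#' Monte-Carlo check of the linear-network feedback correlation
#'
#' In a linear network trained through fixed random feedback, the expected
#' outer product of consecutive teaching signals is proportional to the
#' transpose of the feedback matrix between them,
#' `E[e_l e_{l-1}^T] ~ B_{l,l-1}^T` -- the mechanism by which the eHebb term
#' `-e_l e_{l-1}^T` pushes forward weights toward the feedback transposes.
#' This routine estimates the expectation over random standard-normal inputs
#' and uniform labels and reports, for each hidden layer, the cosine
#' similarity between the flattened estimate and the flattened `B^T`.
#'
#' Only asserted for identity-activation networks; the approximation is not
#' claimed for nonlinear ones.
#'
#' @param state a `plasticity_network` built with `activation = "identity"`
#'   and `feedback_mode = "FA"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed RNG seed.
#' @return named numeric vector of cosine similarities for layers
#'   1..L-1.
#' @export
eq9_check <- function(state, n_samples = 1e5, seed = 1) {
  cfg <- state$config
  if (cfg$activation != "identity")
    stop("the feedback-correlation check applies to identity-activation networks")
  L <- length(state$W)
  d <- cfg$layer_sizes[1]
  n_class <- utils::tail(cfg$layer_sizes, 1)
  acc <- lapply(seq_len(L), function(l)
    matrix(0, cfg$layer_sizes[l + 1], cfg$layer_sizes[l]))
  .with_seed(seed, {
    for (i in seq_len(n_samples)) {
      x <- stats::rnorm(d)
      lab <- sample.int(n_class, 1)
      tr <- forward(state, x)
      et <- propagate_errors(state, tr, output_error(tr, lab))
      for (l in seq_len(L - 1))
        acc[[l]] <- acc[[l]] + .outer_c(et$e[[l + 1]], et$e[[l]])
    }
  })
  cossim <- function(A, B) sum(A * B) / sqrt(sum(A^2) * sum(B^2))
  stats::setNames(
    vapply(seq_len(L - 1), function(l)
      cossim(acc[[l]] / n_samples, t(state$B[[l]])), numeric(1)),
    paste0("layer_", seq_len(L - 1)))
}

#' Largest principal angle between two subspaces
#'
#' Angle between the span of the rows of `W` and the span of the columns of
#' `basis`, from the singular values of the product of their orthonormal
#' bases.
#'
#' @param W k x d matrix whose row space is compared.
#' @param basis d x k matrix of basis columns (e.g. top-k eigenvectors).
#' @return largest principal angle, degrees.
#' @export
principal_subspace_angle <- function(W, basis) {
  qw <- qr.Q(qr(t(W)))
  qb <- qr.Q(qr(basis))
  sv <- svd(t(qw) %*% qb)$d
  acos(min(pmin(sv, 1))) * 180 / pi
}

#' Train a linear compression layer with the pure Oja term
#'
#' Online training of a single k x d linear layer on zero-mean Gaussian
#' inputs with covariance `sigma`, using only plasticity term 9 with an
#' annealed step size `lr0 / (1 + t / anneal)` (the usual Robbins-Monro
#' schedule for stochastic principal-subspace extraction). The rows of `W`
#' converge to an orthonormal basis of the top-k principal subspace of the
#' input covariance.
#'
#' @param sigma input covariance matrix (d x d, positive definite).
#' @param k number of output units (k < d for a compression layer).
#' @param steps number of online updates.
#' @param lr0 initial step size.
#' @param anneal annealing time constant (steps).
#' @param seed RNG seed.
#' @return list with `W` (k x d), `angle` (largest principal angle to the
#'   top-k eigenvector subspace, degrees) and `ew` (mean orthonormality
#'   error over 200 fresh samples).
#' @export
train_oja_layer <- function(sigma, k, steps = 30000, lr0 = 0.02,
                            anneal = 2000, seed = 1) {
  d <- nrow(sigma)
  stopifnot(k < d)
  ch <- chol(sigma)
  eig <- eigen(sigma, symmetric = TRUE)
  .with_seed(seed, {
    W <- .xavier(k, d)
    zero_k <- numeric(k); zero_d <- numeric(d)
    for (t in seq_len(steps)) {
      x <- as.vector(stats::rnorm(d) %*% ch)
      y <- as.vector(W %*% x)
      s <- list(y_pre = x, y_post = y, e_pre = zero_d, e_post = zero_k, W = W)
      W <- W + (lr0 / (1 + t / anneal)) * plasticity_term(9, s)
    }
    ew <- mean(replicate(200, {
      x <- as.vector(stats::rnorm(d) %*% ch)
      z <- as.vector(W %*% x)
      sum((z - as.vector(W %*% (t(W) %*% z)))^2)
    }))
    list(W = W, angle = principal_subspace_angle(W, eig$vectors[, seq_len(k)]),
         ew = ew)
  })
}
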