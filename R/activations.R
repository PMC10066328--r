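# Numerically stable activation primitives.
#
# Every function here accepts real or complex input: the meta-gradient is
# obtained by complex-step differentiation through the unrolled inner loop,
# so the whole forward/backward machinery must be closed under complex
# arithmetic. Branch conditions therefore test Re() only, which keeps each
# branch analytic in a neighbourhood of the real axis.

# log(1 + x), complex-safe (log1p() rejects complex input)
.log1p_c <- function(x) {
  if (is.complex(x)) log(1 + x) else log1p(x)
}

#' Softplus activation
#'
#' Smoothed rectifier \eqn{\sigma(z) = \log(1 + e^{\beta z})/\beta}.
#' Computed in the shifted form \eqn{\max(z,0) + \log(1+e^{-\beta|z|})/\beta}
#' so that large arguments neither overflow nor lose precision.
#'
#' @param z numeric (or complex) vector or matrix of pre-activations.
#' @param beta smoothness parameter \eqn{\beta > 0}; larger values approach
#'   the rectifier \eqn{\max(z, 0)}.
#' @return object of the same shape as `z`.
#' @export
softplus <- function(z, beta = 10) {
  stopifnot(beta > 0)
  bz <- beta * z
  pos <- which(Re(bz) > 0)
  neg <- which(Re(bz) <= 0)  # NaN entries stay NaN via z * NA-safe product
  out <- z * NA_real_
  out[pos] <- z[pos] + .log1p_c(exp(-bz[pos])) / beta
  out[neg] <- .log1p_c(exp(bz[neg])) / beta
  out
}

#' Softplus derivative
#'
#' \eqn{\sigma'(z) = 1/(1 + e^{-\beta z})}, the logistic function of
#' \eqn{\beta z}. Evaluated branch-wise so neither tail overflows.
#'
#' @inheritParams softplus
#' @return object of the same shape as `z`.
#' @export
softplus_grad <- function(z, beta = 10) {
  stopifnot(beta > 0)
  bz <- beta * z
  pos <- which(Re(bz) > 0)
  neg <- which(Re(bz) <= 0)
  out <- z * NA_real_
  out[pos] <- 1 / (1 + exp(-bz[pos]))
  ex <- exp(bz[neg])
  out[neg] <- ex / (1 + ex)
  out
}

# softmax over a vector, shifted by the (real part of the) maximum
.softmax <- function(z) {
  ez <- exp(z - max(Re(z)))
  ez / sum(ez)
}

# log(sum(exp(z))), shifted
.logsumexp <- function(z) {
  m <- max(Re(z))
  m + log(sum(exp(z - m)))
}

# finite for real or complex matrices/vectors
.all_finite <- function(x) {
  if (is.complex(x)) all(is.finite(Re(x))) && all(is.finite(Im(x)))
  else all(is.finite(x))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
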