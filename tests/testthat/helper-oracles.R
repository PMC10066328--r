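# Shared fixtures and independent oracles used across the test files.

# small synthetic sources reused by several tests
tiny_source <- function(input_dim = 12, pool = 20, seed = 2, ...) {
  make_synthetic_source(
    synthetic_task_spec(class_pool_size = pool, input_dim = input_dim, ...),
    seed)
}

# hand-coded forward oracle: explicit matrix products, stable softplus,
# independent of the package's forward()
oracle_forward <- function(W, x, beta = 10) {
  L <- length(W)
  z <- vector("list", L); y <- vector("list", L)
  prev <- x
  for (l in seq_len(L)) {
    z[[l]] <- as.vector(W[[l]] %*% prev)
    if (l < L) {
      y[[l]] <- ifelse(z[[l]] > 0,
                       z[[l]] + log1p(exp(-beta * z[[l]])) / beta,
                       log1p(exp(beta * z[[l]])) / beta)
    } else {
      p <- exp(z[[l]] - max(z[[l]]))
      y[[l]] <- p / sum(p)
    }
    prev <- y[[l]]
  }
  list(z = z, y = y)
}

# loss as a function of the layer-l pre-activation (resuming the forward
# pass from there); used for finite-difference gradient checks
oracle_loss_from_z <- function(W, zl, l, label, beta = 10) {
  L <- length(W)
  z <- zl
  if (l < L) {
    prev <- ifelse(z > 0, z + log1p(exp(-beta * z)) / beta,
                   log1p(exp(beta * z)) / beta)
    for (k in (l + 1):L) {
      z <- as.vector(W[[k]] %*% prev)
      if (k < L) prev <- ifelse(z > 0, z + log1p(exp(-beta * z)) / beta,
                                log1p(exp(beta * z)) / beta)
    }
  }
  m <- max(z)
  m + log(sum(exp(z - m))) - z[label]
}

# central finite differences of oracle_loss_from_z w.r.t. z_l
oracle_fd_gradient <- function(W, z0, l, label, beta = 10, h = 1e-6) {
  vapply(seq_along(z0), function(j) {
    zp <- z0; zm <- z0
    zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
    (oracle_loss_from_z(W, zp, l, label, beta) -
       oracle_loss_from_z(W, zm, l, label, beta)) / (2 * h)
  }, numeric(1))
}

# verbatim matrix-product evaluation of the ten term formulas (a separate
# computational path from the package's scalar-contracted forms)
oracle_term <- function(r, yp, yq, ep, eq, W) {
  ones <- rep(1, length(yq))
  switch(as.character(r),
    "0" = -eq %o% yp,
    "1" = -yq %o% ep,
    "2" = -eq %o% ep,
    "3" = -W,
    "4" = -ones %o% ep,
    "5" = -(eq %o% yp) * sum(ones * yq),
    "6" = -(yq %o% yq) %*% W %*% (ep %o% ep),
    "7" = -(eq %*% t(yq)) %*% W %*% (ep %o% yp),
    "8" = -(yq %o% yp) %*% t(W) %*% (eq %o% ep),
    "9" = yq %o% yp - (yq %o% yq) %*% W
  )
}

# independent online SGD backprop (learning rate lr), mirrors the textbook
# update; used to pin the BP + theta_0 equivalence
oracle_sgd_train <- function(state, task, lr, beta = 10) {
  W <- state$W
  L <- length(W)
  for (i in seq_len(nrow(task$train_x))) {
    x <- task$train_x[i, ]; lab <- task$train_y[i]
    fw <- oracle_forward(W, x, beta)
    e <- vector("list", L)
    e[[L]] <- fw$y[[L]]; e[[L]][lab] <- e[[L]][lab] - 1
    for (l in seq(L - 1, 1)) {
      e[[l]] <- as.vector(t(W[[l + 1]]) %*% e[[l + 1]]) /
        (1 + exp(-beta * fw$z[[l]]))
    }
    for (l in seq_len(L)) {
      pre <- if (l == 1) x else fw$y[[l - 1]]
      W[[l]] <- W[[l]] - lr * (e[[l]] %o% pre)
    }
  }
  W
}

random_signals <- function(n_post = 3, n_pre = 4, seed = 1) {
  set.seed(seed)
  local_signals(y_pre = rnorm(n_pre), y_post = rnorm(n_post),
                e_pre = rnorm(n_pre), e_post = rnorm(n_post),
                W = matrix(rnorm(n_post * n_pre), n_post, n_pre))
}
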