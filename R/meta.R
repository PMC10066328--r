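# The two-level learning scheme: an online inner adaptation loop that trains
# W with the parameterized plasticity rule, and an outer loop that updates
# the shared coefficients Theta by ADAM on an L1-penalized meta-loss.
#
# Meta-gradients are exact derivatives of the meta-loss through the whole
# unrolled inner loop. They are computed by complex-step differentiation:
# the inner loop is re-run with theta_r + i*h for each active coefficient,
# and d(meta-loss)/d(theta_r) = Im(meta-loss)/h. Because every operation in
# the forward pass, error propagation and weight update is analytic (the
# softplus nonlinearity in particular is smooth, so it supports the required
# double differentiation), the complex-step derivative is accurate to
# machine precision -- there is no subtractive cancellation, unlike finite
# differences.

.CSTEP_H <- 1e-20

#' Meta-learning configuration
#'
#' @param network a [network_config()]; the last layer size must be at least
#'   `M` (classes are relabeled 1..M within an episode).
#' @param rule a [plasticity_rule()] or [layer_rule_map()]; its active
#'   coefficients are the meta-parameters.
#' @param source a `task_source` providing episodes.
#' @param episodes number of meta-optimization episodes.
#' @param M,K,Q classes per task, training and query items per class
#'   (defaults 5, 50, 10; the inner loop then takes `M * K = 250` online
#'   steps).
#' @param meta_learning_rate ADAM step size for Theta (default 1e-3).
#' @param l1_lambda L1 penalty coefficient lambda (default 0, as used when
#'   benchmarking single-coefficient rules).
#' @param trial_seed integer seed; all episode task draws and weight
#'   initializations derive from it.
#' @return an object of class `meta_config`.
#' @export
meta_config <- function(network, rule, source, episodes,
                        M = 5, K = 50, Q = 10,
                        meta_learning_rate = 1e-3, l1_lambda = 0,
                        trial_seed = 1) {
  stopifnot(inherits(network, "network_config"))
  if (!inherits(rule, "plasticity_rule") && !inherits(rule, "layer_rule_map"))
    stop("rule must be a plasticity_rule or layer_rule_map")
  stopifnot(inherits(source, "task_source"))
  if (network$layer_sizes[1] != source$input_dim)
    stop("network input dimension must match the task source")
  if (utils::tail(network$layer_sizes, 1) < M)
    stop("output layer must have at least M units")
  if (episodes < 0 || meta_learning_rate <= 0 || l1_lambda < 0)
    stop("invalid meta-optimization parameters")
  structure(list(network = network, rule = rule, source = source,
                 episodes = as.integer(episodes),
                 M = as.integer(M), K = as.integer(K), Q = as.integer(Q),
                 meta_learning_rate = meta_learning_rate,
                 l1_lambda = l1_lambda,
                 trial_seed = as.integer(trial_seed)),
            class = "meta_config")
}

#' Run the online inner adaptation loop
#'
#' Re-initializes the network from scratch (weights are never meta-learned),
#' then performs one forward pass, one backward error propagation and one
#' composed weight update per training sample -- a single epoch at batch
#' size 1, exactly `M * K` updates. Errors are computed with the pre-update
#' weights of the current step, as in the interleaved backward sweep of the
#' adaptation algorithm.
#'
#' Passing a complex `theta` carries exact sensitivity of the final weights
#' to the coefficients through all inner steps (the complex-step mechanism
#' described above); all signals then flow in complex arithmetic.
#'
#' @param rule a [plasticity_rule()] or [layer_rule_map()].
#' @param task an [sample_episode()] task.
#' @param net_config a [network_config()].
#' @param seed seed for the weight/feedback initialization.
#' @param record_diagnostics if `TRUE`, also propagate every error through
#'   the symmetric (backprop) pathway and record per-episode mean alignment
#'   angles and hidden-layer orthonormality errors.
#' @param theta optional length-10 (possibly complex) coefficient vector
#'   overriding the rule's coefficients.
#' @return list with `state` (the trained network), `aborted` (`TRUE` if a
#'   non-finite weight or loss appeared; the returned state is then the last
#'   finite one), `n_updates`, and (if recorded) `alpha` (mean angles for
#'   e_0..e_L, degrees) and `ew` (mean orthonormality error per hidden
#'   layer).
#' @export
run_inner_loop <- function(rule, task, net_config, seed,
                           record_diagnostics = FALSE, theta = NULL) {
  L <- length(net_config$layer_sizes) - 1
  rs <- .as_rule_set(rule, L)
  if (!is.null(theta)) rs$theta <- theta
  state <- init_network(net_config, seed)
  n <- nrow(task$train_x)
  rec_alpha <- if (record_diagnostics) matrix(NA_real_, n, L + 1)
  rec_ew <- if (record_diagnostics && L > 1) matrix(NA_real_, n, L - 1)
  aborted <- FALSE
  for (i in seq_len(n)) {
    tr <- forward(state, task$train_x[i, ])
    eL <- output_error(tr, task$train_y[i])
    if (!.all_finite(eL)) {  # activations overflowed even if W is finite
      aborted <- TRUE
      break
    }
    et <- propagate_errors(state, tr, eL)
    if (record_diagnostics) {
      rec_alpha[i, ] <- .trace_angles(state, tr, et)
      if (L > 1) rec_ew[i, ] <- vapply(seq_len(L - 1), function(l)
        orthonormality_error(state, tr, l), numeric(1))
    }
    for (l in seq_len(L)) {
      s <- list(y_pre = if (l == 1) tr$y0 else tr$y[[l - 1]],
                y_post = tr$y[[l]],
                e_pre = et$e[[l]], e_post = et$e[[l + 1]],
                W = state$W[[l]])
      act <- rs$active_by_layer[[l]]
      dW <- state$W[[l]] * 0
      for (r in act) {
        th <- rs$theta[r + 1]
        if (Re(th) != 0 || (is.complex(th) && Im(th) != 0))
          dW <- dW + th * plasticity_term(r, s)
      }
      state$W[[l]] <- state$W[[l]] + dW
    }
    if (!all(vapply(state$W, .all_finite, logical(1)))) {
      aborted <- TRUE
      break
    }
  }
  out <- list(state = state, aborted = aborted,
              n_updates = if (aborted) i else n)
  if (record_diagnostics) {
    out$alpha <- colMeans(rec_alpha, na.rm = TRUE)
    out$ew <- if (L > 1) colMeans(rec_ew, na.rm = TRUE) else numeric(0)
  }
  out
}

# FA-vs-BP angles of one recorded step (NA where a signal vanishes);
# returns alpha_0..alpha_L in degrees. For a BP-mode state both pathways
# coincide and all angles are zero.
.trace_angles <- function(state, tr, et_fa) {
  L <- length(state$W)
  if (state$config$feedback_mode == "BP") return(numeric(L + 1))
  bp_state <- state
  bp_state$config$feedback_mode <- "BP"
  et_bp <- propagate_errors(bp_state, tr, et_fa$e[[L + 1]])
  a <- vapply(0:(L - 1), function(l)
    alignment_angle(Re(et_fa$e[[l + 1]]), Re(et_bp$e[[l + 1]])),
    numeric(1))
  c(a, 0)  # both pathways share e_L, so the top angle is 0 by definition
}

# mean cross-entropy and accuracy of a trained state on a query set
.query_metrics <- function(state, query_x, query_y) {
  n <- nrow(query_x)
  ce <- 0
  correct <- 0L
  for (i in seq_len(n)) {
    tr <- forward(state, query_x[i, ])
    ce <- ce + cross_entropy(tr, query_y[i])
    pred <- which.max(Re(tr$y[[length(tr$y)]]))
    if (length(pred) == 1 && pred == query_y[i]) correct <- correct + 1L
  }
  list(ce = ce / n, accuracy = correct / n)
}

#' Meta-loss of a trained network
#'
#' Mean cross-entropy of the trained network over the query set plus the L1
#' penalty `lambda * sum(|theta|)`. The subgradient of `|.|` at zero is
#' taken as zero when the penalty is differentiated.
#'
#' @param state a trained `plasticity_network`.
#' @param query_x,query_y query inputs (rows) and labels.
#' @param coeffs the rule whose coefficients are penalized.
#' @param l1_lambda penalty coefficient.
#' @return scalar meta-loss.
#' @export
meta_loss <- function(state, query_x, query_y, coeffs, l1_lambda = 0) {
  if (is.null(nrow(query_x)) || nrow(query_x) == 0)
    stop("query set must be non-empty")
  qm <- .query_metrics(state, query_x, query_y)
  qm$ce + l1_lambda * sum(abs(coeffs$theta[coeffs$active + 1]))
}

# one ADAM update of the active coordinates (original moment defaults)
.adam_step <- function(theta, grad, active, opt,
                       lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  idx <- active + 1
  opt$t <- opt$t + 1
  opt$m[idx] <- beta1 * opt$m[idx] + (1 - beta1) * grad[idx]
  opt$v[idx] <- beta2 * opt$v[idx] + (1 - beta2) * grad[idx]^2
  mhat <- opt$m[idx] / (1 - beta1^opt$t)
  vhat <- opt$v[idx] / (1 - beta2^opt$t)
  theta[idx] <- theta[idx] - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, opt = opt)
}

#' Exact meta-gradient of the meta-loss with respect to Theta
#'
#' Differentiates the query cross-entropy through the full unrolled inner
#' loop by the complex-step method (one complex re-run per active
#' coefficient) and adds the L1 subgradient `lambda * sign(theta_r)`
#' analytically.
#'
#' @inheritParams run_inner_loop
#' @param l1_lambda penalty coefficient.
#' @return list with `grad` (length-10 vector, zeros at inactive indices)
#'   and `aborted` (`TRUE` if any perturbed run blew up).
#' @export
meta_gradient <- function(rule, task, net_config, seed, l1_lambda = 0) {
  L <- length(net_config$layer_sizes) - 1
  rs <- .as_rule_set(rule, L)
  grad <- numeric(10)
  h <- .CSTEP_H
  for (r in rs$active) {
    th <- as.complex(rs$theta)
    th[r + 1] <- th[r + 1] + complex(imaginary = h)
    res <- run_inner_loop(rule, task, net_config, seed, theta = th)
    if (res$aborted) return(list(grad = grad, aborted = TRUE))
    qm <- .query_metrics(res$state, task$query_x, task$query_y)
    if (!.all_finite(qm$ce)) return(list(grad = grad, aborted = TRUE))
    grad[r + 1] <- Im(qm$ce) / h + l1_lambda * sign(Re(rs$theta[r + 1]))
  }
  list(grad = grad, aborted = FALSE)
}

#' Meta-train the plasticity coefficients
#'
#' Runs the outer meta-optimization loop: each episode samples a fresh task,
#' re-initializes the network, runs the online inner loop, evaluates the
#' L1-penalized meta-loss on the task's query set, and takes one ADAM step
#' on the active coefficients using the exact meta-gradient through the
#' unrolled inner loop. Episodes whose inner loop produces non-finite
#' weights are recorded as aborted and skipped (no coefficient update); the
#' run continues.
#'
#' @param config a [meta_config()].
#' @return an object of class `meta_fit`: list with `history` (one row per
#'   episode: meta-loss, meta-accuracy, the coefficient snapshot used in
#'   that episode, per-layer mean alignment angles `alpha_0..alpha_L` and
#'   hidden-layer orthonormality errors `ew_1..ew_{L-1}`), the final `rule`,
#'   and the `config`.
#' @export
meta_train <- function(config) {
  stopifnot(inherits(config, "meta_config"))
  L <- length(config$network$layer_sizes) - 1
  rs <- .as_rule_set(config$rule, L)
  rule <- config$rule
  seeds <- .with_seed(config$trial_seed, {
    list(task = sample.int(.Machine$integer.max, max(config$episodes, 1)),
         net = sample.int(.Machine$integer.max, max(config$episodes, 1)))
  })
  opt <- list(m = numeric(10), v = numeric(10), t = 0)
  rows <- vector("list", config$episodes)
  for (ep in seq_len(config$episodes)) {
    task <- sample_episode(config$source, config$M, config$K, config$Q,
                           seeds$task[ep])
    res <- run_inner_loop(rule, task, config$network, seeds$net[ep],
                          record_diagnostics = TRUE)
    row <- c(list(episode = ep, aborted = res$aborted,
                  meta_loss = NA_real_, meta_accuracy = NA_real_),
             as.list(stats::setNames(rule$theta, paste0("theta_", 0:9))),
             as.list(stats::setNames(rep(NA_real_, L + 1),
                                     paste0("alpha_", 0:L))),
             if (L > 1) as.list(stats::setNames(rep(NA_real_, L - 1),
                                                paste0("ew_", seq_len(L - 1)))))
    if (!res$aborted) {
      qm <- .query_metrics(res$state, task$query_x, task$query_y)
      if (!is.finite(Re(qm$ce))) res$aborted <- row$aborted <- TRUE
    }
    if (!res$aborted) {
      row$meta_loss <- qm$ce +
        config$l1_lambda * sum(abs(rule$theta[rs$active + 1]))
      row$meta_accuracy <- qm$accuracy
      row[paste0("alpha_", 0:L)] <- as.list(res$alpha)
      if (L > 1) row[paste0("ew_", seq_len(L - 1))] <- as.list(res$ew)
      g <- meta_gradient(rule, task, config$network, seeds$net[ep],
                         config$l1_lambda)
      if (!g$aborted) {
        upd <- .adam_step(rule$theta, g$grad, rs$active, opt,
                          config$meta_learning_rate)
        rule$theta <- stats::setNames(upd$theta, names(rule$theta))
        opt <- upd$opt
      } else {
        row$aborted <- TRUE
      }
    }
    rows[[ep]] <- row
  }
  history <- if (config$episodes > 0)
    do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  else .empty_history(L)
  structure(list(history = history, rule = rule, config = config),
            class = "meta_fit")
}

.empty_history <- function(L) {
  cols <- c("episode", "aborted", "meta_loss", "meta_accuracy",
            paste0("theta_", 0:9), paste0("alpha_", 0:L),
            if (L > 1) paste0("ew_", seq_len(L - 1)))
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                      cols))
  df$aborted <- logical(0)
  df
}

#' @export
print.meta_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<meta_fit> %d episodes (%d aborted)\n",
              nrow(h), sum(h$aborted)))
  if (nrow(h) > 0) {
    last <- utils::tail(h, min(10, nrow(h)))
    cat(sprintf("  final meta-accuracy (last %d episodes): %.3f\n",
                nrow(last), mean(last$meta_accuracy, na.rm = TRUE)))
    th <- x$rule$theta[x$rule$active + 1]
    cat("  theta:", paste(sprintf("%s=%.4g", names(th), th),
                          collapse = " "), "\n")
  }
  invisible(x)
}
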