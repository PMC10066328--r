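test_that("a zero rule leaves the network untrained at chance accuracy", {
  src <- tiny_source(input_dim = 12, seed = 31)
  net <- network_config(c(12, 8, 4))  # output = M so chance = 1/M
  rule <- plasticity_rule(0:9)        # all coefficients zero
  accs <- vapply(1:5, function(s) {
    task <- sample_episode(src, M = 4, K = 5, Q = 25, seed = s)
    res <- run_inner_loop(rule, task, net, seed = s + 100)
    st0 <- init_network(net, s + 100)
    expect_identical(res$state$W, st0$W)
    mean(vapply(seq_len(nrow(task$query_x)), function(i) {
      tr <- forward(res$state, task$query_x[i, ])
      which.max(tr$y[[2]]) == task$query_y[i]
    }, logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.15)
})

test_that("the inner loop performs exactly M*K single-sample updates", {
  src <- tiny_source(input_dim = 8, seed = 5)
  task <- sample_episode(src, M = 5, K = 50, Q = 2, seed = 9)
  expect_equal(nrow(task$train_x), 250)
  res <- run_inner_loop(named_rule("FA_baseline"), task,
                        network_config(c(8, 6, 5)), seed = 3)
  expect_equal(res$n_updates, 250)
  expect_false(res$aborted)
})

test_that("a single inner step equals a hand-applied composed update", {
  src <- tiny_source(input_dim = 6, seed = 41)
  task <- sample_episode(src, M = 2, K = 1, Q = 1, seed = 7)
  task$train_x <- task$train_x[1, , drop = FALSE]
  task$train_y <- task$train_y[1]
  net <- network_config(c(6, 2, 2), feedback_mode = "FA")
  rule <- plasticity_rule(c(0, 2, 9), c(1e-2, 5e-3, 2e-3))
  res <- run_inner_loop(rule, task, net, seed = 19)
  st0 <- init_network(net, 19)
  tr <- forward(st0, task$train_x[1, ])
  et <- propagate_errors(st0, tr, output_error(tr, task$train_y[1]))
  for (l in 1:2) {
    s <- local_signals(y_pre = if (l == 1) tr$y0 else tr$y[[l - 1]],
                       y_post = tr$y[[l]], e_pre = et$e[[l]],
                       e_post = et$e[[l + 1]], W = st0$W[[l]])
    expect_equal(res$state$W[[l]], st0$W[[l]] + compose_update(rule, s),
                 tolerance = 1e-12)
  }
})

test_that("meta-loss is query cross-entropy plus the exact L1 penalty", {
  # two query points with hand-computable softmax outputs
  net <- network_config(c(2, 3, 2))
  st <- init_network(net, 1)
  st$W[[1]] <- matrix(0, 3, 2)
  st$W[[2]] <- matrix(0, 2, 3)
  qx <- rbind(c(0.2, 0.8), c(0.9, 0.1))
  qy <- c(1, 2)
  # zero weights: softmax is uniform, CE = log(2) for each point
  rule <- plasticity_rule(c(0, 2), c(1e-3, -2e-3))
  expect_equal(meta_loss(st, qx, qy, rule, l1_lambda = 0), log(2),
               tolerance = 1e-10)
  expect_equal(meta_loss(st, qx, qy, rule, l1_lambda = 0.5),
               log(2) + 0.5 * (1e-3 + 2e-3), tolerance = 1e-10)
  expect_error(meta_loss(st, qx[0, , drop = FALSE], integer(0), rule),
               "non-empty")
})

test_that("zero episodes is a no-op with an empty history", {
  src <- tiny_source(input_dim = 8, seed = 3)
  cfg <- meta_config(network_config(c(8, 6, 4)), named_rule("eHebb"), src,
                     episodes = 0, M = 3, K = 2, Q = 1)
  fit <- meta_train(cfg)
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$rule$theta, named_rule("eHebb")$theta)
})

test_that("meta-training is reproducible from the trial seed", {
  src <- tiny_source(input_dim = 10, seed = 6)
  cfg <- meta_config(network_config(c(10, 7, 5), feedback_mode = "FA"),
                     named_rule("eHebb"), src, episodes = 4,
                     M = 3, K = 3, Q = 2, trial_seed = 77)
  f1 <- meta_train(cfg)
  f2 <- meta_train(cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$rule$theta, f2$rule$theta)
  cfg$trial_seed <- 78
  expect_false(identical(meta_train(cfg)$history, f1$history))
})

test_that("BP mode with only theta_0 is step-for-step plain SGD backprop", {
  src <- tiny_source(input_dim = 12, seed = 2)
  task <- sample_episode(src, M = 3, K = 4, Q = 2, seed = 7)
  net <- network_config(c(12, 8, 6, 3), feedback_mode = "BP")
  res <- run_inner_loop(named_rule("FA_baseline"), task, net, seed = 3)
  W_sgd <- oracle_sgd_train(init_network(net, 3), task, lr = 1e-3)
  expect_equal(res$state$W, W_sgd, tolerance = 1e-12)
})

test_that("an exploding rule aborts the episode but not the run", {
  src <- tiny_source(input_dim = 10, seed = 13)
  net <- network_config(c(10, 8, 5), feedback_mode = "FA")
  # anti-decay: W grows by a factor 1e20 per step, overflowing within steps
  rule <- plasticity_rule(3, -1e20)
  cfg <- meta_config(net, rule, src, episodes = 3, M = 3, K = 10, Q = 2,
                     trial_seed = 1)
  fit <- meta_train(cfg)
  expect_equal(nrow(fit$history), 3)
  expect_true(all(fit$history$aborted))
  # no coefficient update was taken on aborted episodes
  expect_identical(fit$rule$theta, rule$theta)
})

test_that("meta-training the learning rate under backprop improves accuracy", {
  src <- make_synthetic_source(
    synthetic_task_spec(class_pool_size = 20, input_dim = 64), 11)
  net <- network_config(c(64, 32, 24, 16, 8), feedback_mode = "BP")
  deltas <- vapply(1:5, function(s) {
    fit <- meta_train(meta_config(net, named_rule("FA_baseline"), src,
                                  episodes = 100, M = 5, K = 10, Q = 4,
                                  trial_seed = s))
    h <- fit$history
    mean(utils::tail(h$meta_accuracy, 10), na.rm = TRUE) -
      mean(utils::head(h$meta_accuracy, 10), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(deltas > 0))
  expect_gt(mean(deltas), 0.1)
})

test_that("L1 regularization sparsifies the surviving pool terms", {
  src <- make_synthetic_source(
    synthetic_task_spec(class_pool_size = 20, input_dim = 36), 11)
  net <- network_config(c(36, 24, 16, 8), feedback_mode = "FA")
  surviving <- function(theta) {
    a <- abs(theta)
    sum(a >= 0.1 * max(a))
  }
  counts <- sapply(c(0, 0.01, 0.1), function(lam) {
    vapply(1:3, function(s) {
      fit <- meta_train(meta_config(net, named_rule("pool"), src,
                                    episodes = 250, M = 3, K = 6, Q = 4,
                                    l1_lambda = lam, trial_seed = s))
      surviving(fit$rule$theta)
    }, numeric(1))
  })
  means <- colMeans(counts)
  expect_true(all(diff(means) <= 0))
  expect_lt(means[3], means[1])
})
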