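test_that("episodes have exact per-class counts, bounds and determinism", {
  src <- tiny_source(input_dim = 16, pool = 20, seed = 1)
  task <- sample_episode(src, M = 5, K = 50, Q = 10, seed = 4)
  expect_equal(nrow(task$train_x), 250)
  expect_equal(nrow(task$query_x), 50)
  expect_equal(as.vector(table(task$train_y)), rep(50, 5))
  expect_equal(as.vector(table(task$query_y)), rep(10, 5))
  expect_true(all(task$train_x >= 0 & task$train_x <= 1))
  expect_true(all(task$class_ids %in% seq_len(20)))
  expect_equal(anyDuplicated(task$class_ids), 0)
  expect_identical(task, sample_episode(src, 5, 50, 10, seed = 4))
  expect_false(identical(task$train_x,
                         sample_episode(src, 5, 50, 10, seed = 5)$train_x))
  expect_error(sample_episode(src, M = 21, K = 1, Q = 1, seed = 1),
               "classes")
})

test_that("class draws stay inside the pool across many episodes", {
  src <- tiny_source(input_dim = 4, pool = 47, seed = 9)
  ids <- unlist(lapply(1:200, function(s)
    sample_episode(src, M = 5, K = 1, Q = 1, seed = s)$class_ids))
  expect_true(all(ids >= 1 & ids <= 47))
  expect_gt(length(unique(ids)), 40)  # the sampler visits the whole pool
})

test_that("noiseless synthetic samples equal their class prototype", {
  spec <- synthetic_task_spec(class_pool_size = 20, input_dim = 25,
                              noise_scale = 0)
  src <- make_synthetic_source(spec, 8)
  task <- sample_episode(src, M = 3, K = 4, Q = 2, seed = 2)
  for (m in 1:3) {
    rows <- task$train_x[task$train_y == m, , drop = FALSE]
    proto <- src$prototypes[, task$class_ids[m]]
    expect_true(all(abs(sweep(rows, 2, proto)) < 1e-14))
  }
})

test_that("different generator seeds give different prototypes", {
  spec <- synthetic_task_spec(class_pool_size = 20, input_dim = 30)
  s1 <- make_synthetic_source(spec, 1)
  s2 <- make_synthetic_source(spec, 2)
  expect_false(identical(s1$prototypes, s2$prototypes))
  # no accidental class collision within a source
  d <- as.matrix(stats::dist(t(s1$prototypes)))
  expect_gt(min(d[upper.tri(d)]), 0.5)
  # glyph structure produces sparse bright-on-dark prototypes
  g <- make_synthetic_source(
    synthetic_task_spec(class_pool_size = 20, input_dim = 49,
                        structure = "blob_glyphs"), 3)
  expect_lt(stats::median(g$prototypes), 0.5)
  expect_gt(max(g$prototypes), 0.9)
})

test_that("IDX files round-trip through write and read", {
  n <- 12; d <- 16
  set.seed(10)
  imgs <- matrix(round(runif(n * d) * 255) / 255, n, d)
  labs <- sample(0:4, n, replace = TRUE)
  fi <- withr::local_tempfile(fileext = ".idx")
  fl <- withr::local_tempfile(fileext = ".idx")
  write_idx(imgs, fi, "images")
  write_idx(labs, fl, "labels")
  expect_equal(read_idx(fi), imgs, tolerance = 1e-12)
  expect_equal(read_idx(fl), labs)
  src <- idx_source(fi, fl)
  expect_equal(src$n_classes, length(unique(labs)))
  expect_equal(src$input_dim, d)
})

test_that("stored-dataset episodes keep train and query items disjoint", {
  spec <- synthetic_task_spec(class_pool_size = 20, input_dim = 16)
  dir <- withr::local_tempdir()
  materialize_source(make_synthetic_source(spec, 4), dir,
                     n_per_class = 12, seed = 5)
  src <- idx_source(file.path(dir, "images.idx"),
                    file.path(dir, "labels.idx"))
  task <- sample_episode(src, M = 4, K = 8, Q = 4, seed = 6)
  keys_train <- apply(task$train_x, 1, paste, collapse = ",")
  keys_query <- apply(task$query_x, 1, paste, collapse = ",")
  expect_length(intersect(keys_train, keys_query), 0)
  expect_equal(anyDuplicated(c(keys_train, keys_query)), 0)
  expect_error(sample_episode(src, M = 4, K = 10, Q = 4, seed = 1), "items")
})

test_that("default tasks are backprop-learnable and harder with more noise", {
  # full study scale: 5-layer 784-unit net, theta_0 = 1e-3, 250 samples
  net <- network_config(c(784, 170, 130, 100, 70, 47), feedback_mode = "BP")
  rule <- named_rule("FA_baseline")
  acc <- sapply(c(0.1, 0.2, 0.3), function(ns) {
    vapply(1:3, function(s) {
      src <- make_synthetic_source(
        synthetic_task_spec(noise_scale = ns), s)
      task <- sample_episode(src, M = 5, K = 50, Q = 10, seed = s + 100)
      res <- run_inner_loop(rule, task, net, seed = s + 200)
      st <- res$state
      mean(vapply(seq_len(nrow(task$query_x)), function(i) {
        tr <- forward(st, task$query_x[i, ])
        which.max(tr$y[[5]]) == task$query_y[i]
      }, logical(1)))
    }, numeric(1))
  })
  means <- colMeans(acc)
  # calibrated learnability at the default noise level: well above 1/M = 0.2
  expect_gt(means[2], 0.35)
  # difficulty is monotone in the noise scale
  expect_true(all(diff(means) <= 0))
})
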