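test_that("initialization produces the documented shapes, deterministically", {
  cfg <- network_config(c(784, 170, 130, 100, 70, 47))
  st <- init_network(cfg, 7)
  expect_length(st$W, 5)
  expect_length(st$B, 5)
  expect_equal(lapply(st$W, dim),
               list(c(170L, 784L), c(130L, 170L), c(100L, 130L),
                    c(70L, 100L), c(47L, 70L)))
  expect_equal(lapply(st$B, dim),
               lapply(st$W, function(w) rev(dim(w))))
  expect_identical(st, init_network(cfg, 7))
  expect_false(identical(st$W, init_network(cfg, 8)$W))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(network_config(c(10, 5)), "at least 2 layers")
  expect_error(network_config(c(10, 0, 5)), "positive")
  expect_error(network_config(c(10, 5, 3), beta = -1), "beta")
  st <- init_network(network_config(c(4, 3, 2)), 1)
  expect_error(forward(st, rep(0, 5)), "dimension")
  tr <- forward(st, runif(4))
  expect_error(output_error(tr, 3), "label")
  expect_error(output_error(tr, 0), "label")
})

test_that("fixed random feedback is statistically independent of W^T", {
  cors <- vapply(1:100, function(s) {
    st <- init_network(network_config(c(10, 8, 6)), s)
    stats::cor(as.vector(st$B[[2]]), as.vector(t(st$W[[2]])))
  }, numeric(1))
  # mean Frobenius correlation indistinguishable from 0 over 100 seeds
  expect_lt(abs(mean(cors)) / (stats::sd(cors) / sqrt(100)), 3)
})

test_that("forward pass matches an independent matrix-product oracle", {
  cfg <- network_config(c(3, 4, 2))
  st <- init_network(cfg, 42)
  set.seed(9)
  x <- rnorm(3)
  tr <- forward(st, x)
  orc <- oracle_forward(st$W, x, cfg$beta)
  for (l in 1:2) {
    expect_equal(tr$z[[l]], orc$z[[l]], tolerance = 1e-12)
    expect_equal(tr$y[[l]], orc$y[[l]], tolerance = 1e-12)
  }
  expect_equal(sum(tr$y[[2]]), 1, tolerance = 1e-12)
  expect_true(all(tr$y[[2]] > 0))
})

test_that("zero weights give the softplus fixed image and a uniform output", {
  cfg <- network_config(c(6, 5, 4))
  st <- init_network(cfg, 1)
  st$W <- lapply(st$W, function(w) w * 0)
  tr <- forward(st, runif(6))
  expect_equal(tr$z[[1]], rep(0, 5))
  expect_equal(tr$y[[1]], rep(log(2) / 10, 5), tolerance = 1e-14)
  expect_equal(tr$y[[2]], rep(1 / 4, 4), tolerance = 1e-14)
})

test_that("softplus is overflow-safe and matches its large-argument form", {
  expect_equal(softplus(5, beta = 10), 5 + log1p(exp(-50)) / 10,
               tolerance = 1e-12)
  expect_equal(softplus(1000, beta = 10), 1000)
  expect_true(is.finite(softplus(-1000, beta = 10)))
  expect_equal(softplus_grad(1000, beta = 10), 1)
  expect_equal(softplus_grad(-1000, beta = 10), 0)
})

test_that("output error has the softmax cross-entropy closed forms", {
  st <- init_network(network_config(c(3, 4, 5)), 3)
  tr <- forward(st, runif(3))
  # perfect prediction: zero error
  tr_perfect <- tr
  tr_perfect$y[[2]] <- c(0, 1, 0, 0, 0)
  expect_equal(output_error(tr_perfect, 2), rep(0, 5))
  # uniform prediction over 5 classes
  tr_unif <- tr
  tr_unif$y[[2]] <- rep(0.2, 5)
  expect_equal(output_error(tr_unif, 1), c(-0.8, 0.2, 0.2, 0.2, 0.2))
  # random case vs finite differences of CE(softmax(z_L))
  g_fd <- oracle_fd_gradient(st$W, tr$z[[2]], 2, 4)
  expect_equal(output_error(tr, 4), g_fd, tolerance = 1e-6)
})

test_that("error propagation is linear in e_L and vanishes with it", {
  st <- init_network(network_config(c(6, 5, 4, 3), feedback_mode = "FA"), 5)
  tr <- forward(st, runif(6))
  e1 <- rnorm(3); e2 <- rnorm(3)
  et1 <- propagate_errors(st, tr, e1)
  et2 <- propagate_errors(st, tr, e2)
  et12 <- propagate_errors(st, tr, 2 * e1 - 3 * e2)
  for (l in 1:4) {
    expect_equal(et12$e[[l]], 2 * et1$e[[l]] - 3 * et2$e[[l]],
                 tolerance = 1e-12)
  }
  et0 <- propagate_errors(st, tr, rep(0, 3))
  expect_true(all(vapply(et0$e, function(v) all(v == 0), logical(1))))
})

test_that("FA and BP traces share the top error but diverge below", {
  st <- init_network(network_config(c(20, 15, 12, 10, 8, 5),
                                    feedback_mode = "FA"), 11)
  tr <- forward(st, runif(20))
  a <- layer_alignment(st, tr, 2)
  expect_identical(unname(a[["alpha_5"]]), 0)
  expect_true(all(a[paste0("alpha_", 1:4)] > 5))
})

test_that("state serialization round-trips exactly", {
  st <- init_network(network_config(c(6, 5, 4, 3), feedback_mode = "FA",
                                    beta = 7), 13)
  f <- withr::local_tempfile(fileext = ".json")
  write_network_state(st, f)
  st2 <- read_network_state(f)
  expect_identical(st$W, st2$W)
  expect_identical(st$B, st2$B)
  expect_equal(st$config, st2$config)
})

test_that("BP mode reads feedback as a live view of the current weights", {
  st <- init_network(network_config(c(4, 3, 2), feedback_mode = "BP"), 1)
  expect_identical(feedback_matrix(st, 2), t(st$W[[2]]))
  st$W[[2]] <- st$W[[2]] + 1
  expect_identical(feedback_matrix(st, 2), t(st$W[[2]]))
})
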