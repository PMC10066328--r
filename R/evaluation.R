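# Multi-trial orchestration, bootstrap confidence intervals, and the
# benchmark experiment recipes.

#' Run independent meta-training trials
#'
#' Repeats [meta_train()] with trial seeds derived from `base_seed` by a
#' fixed counter scheme (`base_seed + (i - 1) * 10007`). A failing trial is
#' recorded and the remaining trials proceed.
#'
#' @param config a [meta_config()]; its `trial_seed` is overridden per trial.
#' @param n_trials number of trials (protocol default 20).
#' @param base_seed integer base seed.
#' @return an object of class `trial_set`: list of `meta_fit`s (or `NULL`
#'   for failed trials), the seeds, and the config.
#' @export
run_trials <- function(config, n_trials = 20, base_seed = 1) {
  stopifnot(inherits(config, "meta_config"), n_trials >= 1)
  seeds <- base_seed + (seq_len(n_trials) - 1) * 10007L
  trials <- lapply(seeds, function(s) {
    cfg <- config
    cfg$trial_seed <- as.integer(s)
    tryCatch(meta_train(cfg), error = function(e) {
      warning(sprintf("trial with seed %d failed: %s", s, conditionMessage(e)))
      NULL
    })
  })
  structure(list(trials = trials, seeds = seeds, config = config),
            class = "trial_set")
}

#' Combined per-episode history of a trial set
#'
#' @param ts a `trial_set`.
#' @return data frame of all trial histories with a `trial` column.
#' @export
trial_history <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  ok <- which(!vapply(ts$trials, is.null, logical(1)))
  do.call(rbind, lapply(ok, function(i) {
    h <- ts$trials[[i]]$history
    if (nrow(h) > 0) cbind(trial = i, h) else NULL
  }))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the values with replacement `n_boot` times and returns the mean
#' with percentile bounds (protocol defaults: 98% level, 500 resamples).
#'
#' @param values numeric vector (e.g. one value per trial).
#' @param level confidence level in (0, 1).
#' @param n_boot number of bootstrap resamples.
#' @param seed optional RNG seed for the resampling.
#' @return list with `mean`, `lower`, `upper`, `level`.
#' @export
bootstrap_ci <- function(values, level = 0.98, n_boot = 500, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to bootstrap")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  boot <- function() {
    stats <- replicate(n_boot, mean(sample(values, replace = TRUE)))
    q <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    list(mean = mean(values), lower = q[1], upper = q[2], level = level)
  }
  if (is.null(seed)) boot() else .with_seed(seed, boot())
}

#' Per-episode aggregate with bootstrap band
#'
#' @param ts a `trial_set`.
#' @param metric history column to aggregate (e.g. `"meta_accuracy"`).
#' @inheritParams bootstrap_ci
#' @return data frame with columns `episode`, `mean`, `lower`, `upper`.
#' @export
aggregate_episodes <- function(ts, metric = "meta_accuracy", level = 0.98,
                               n_boot = 500, seed = 1) {
  h <- trial_history(ts)
  if (is.null(h) || !metric %in% names(h)) stop("metric not found in history")
  eps <- sort(unique(h$episode))
  rows <- lapply(seq_along(eps), function(i) {
    v <- h[h$episode == eps[i], metric]
    ci <- bootstrap_ci(v, level, n_boot, seed + i)
    data.frame(episode = eps[i], mean = ci$mean,
               lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, rows)
}

#' Default layer-rule assignments for the 3-layer alignment experiment
#'
#' The seven assignments of a 3-layer network in which each weight matrix is
#' trained either with the feedback-alignment baseline (term 0) or with the
#' eHebb rule (terms 0 and 2): the all-baseline row, each single layer
#' switched to eHebb, each pair, and the all-eHebb row. The single
#' assignment "eHebb on the first layer only" is excluded because the
#' first-layer pre-synaptic error is synthetic.
#'
#' @return list of logical length-3 vectors (`TRUE` = eHebb on that layer).
#' @export
default_assignments <- function() {
  list(c(FALSE, FALSE, FALSE),
       c(FALSE, TRUE, FALSE),
       c(FALSE, FALSE, TRUE),
       c(TRUE, TRUE, FALSE),
       c(FALSE, TRUE, TRUE),
       c(TRUE, FALSE, TRUE),
       c(TRUE, TRUE, TRUE))
}

#' Per-layer rule-assignment experiment
#'
#' For each assignment of baseline-vs-eHebb rules to the layers of a
#' 3-layer network, meta-trains the shared coefficients (theta_0, theta_2;
#' lambda = 0) and reports the alignment angles `alpha_0, alpha_1, alpha_2`
#' averaged over the episodes after a burn-in period.
#'
#' @param source a `task_source`.
#' @param assignments list of logical vectors as in [default_assignments()];
#'   each must have one entry per weight matrix.
#' @param layer_sizes network dimensions (default `c(784, 130, 70, 47)`).
#' @param episodes meta-training episodes per assignment (default 500).
#' @param burn_in episodes discarded before averaging (default 100; must be
#'   smaller than `episodes`).
#' @param M,K,Q episode shape.
#' @param meta_learning_rate ADAM step size.
#' @param base_seed seed.
#' @return data frame with one row per assignment: the assignment label and
#'   mean `alpha_0`, `alpha_1`, `alpha_2` (degrees).
#' @export
layer_assignment_experiment <- function(source,
                                        assignments = default_assignments(),
                                        layer_sizes = c(784, 130, 70, 47),
                                        episodes = 500, burn_in = 100,
                                        M = 5, K = 50, Q = 10,
                                        meta_learning_rate = 1e-3,
                                        base_seed = 1) {
  if (burn_in >= episodes)
    stop("burn_in must leave a non-empty averaging window")
  L <- length(layer_sizes) - 1
  net <- network_config(layer_sizes, feedback_mode = "FA")
  rows <- lapply(seq_along(assignments), function(i) {
    a <- assignments[[i]]
    if (length(a) != L)
      stop(sprintf("assignment %d has %d entries for %d layers", i,
                   length(a), L))
    map <- layer_rule_map(lapply(a, function(e) if (e) c(0L, 2L) else 0L))
    cfg <- meta_config(net, map, source, episodes, M = M, K = K, Q = Q,
                       meta_learning_rate = meta_learning_rate,
                       l1_lambda = 0, trial_seed = base_seed + i)
    fit <- meta_train(cfg)
    h <- fit$history[fit$history$episode > burn_in & !fit$history$aborted, ]
    out <- data.frame(assignment = paste(ifelse(a, "eHebb", "FA"),
                                         collapse = "/"))
    for (l in 0:(L - 1))
      out[[paste0("alpha_", l)]] <- mean(h[[paste0("alpha_", l)]],
                                         na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}

#' Online training benchmark of a fixed rule
#'
#' Trains a freshly initialized network online on a single stream (one pass,
#' batch size one) with fixed coefficients -- no meta-optimization -- and
#' records the running prediction accuracy. This is the single-task
#' benchmark used to compare learning speed of fixed rules on a 10-way
#' stream.
#'
#' @param rule a [plasticity_rule()].
#' @param source a `task_source`.
#' @param net_config a [network_config()].
#' @param n_samples stream length.
#' @param M number of classes drawn for the stream.
#' @param seed RNG seed.
#' @param window trailing window for the running accuracy.
#' @return data frame with columns `sample` and `running_accuracy`.
#' @export
online_benchmark <- function(rule, source, net_config, n_samples = 1000,
                             M = 10, seed = 1, window = 100) {
  K <- ceiling(n_samples / M)
  task <- sample_episode(source, M, K, Q = 1, seed = seed)
  L <- length(net_config$layer_sizes) - 1
  rs <- .as_rule_set(rule, L)
  state <- init_network(net_config, seed + 1)
  n <- min(n_samples, nrow(task$train_x))
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr <- forward(state, task$train_x[i, ])
    correct[i] <- which.max(tr$y[[L]]) == task$train_y[i]
    et <- propagate_errors(state, tr, output_error(tr, task$train_y[i]))
    for (l in seq_len(L)) {
      s <- list(y_pre = if (l == 1) tr$y0 else tr$y[[l - 1]],
                y_post = tr$y[[l]], e_pre = et$e[[l]], e_post = et$e[[l + 1]],
                W = state$W[[l]])
      dW <- state$W[[l]] * 0
      for (r in rs$active_by_layer[[l]]) {
        th <- rs$theta[r + 1]
        if (th != 0) dW <- dW + th * plasticity_term(r, s)
      }
      state$W[[l]] <- state$W[[l]] + dW
    }
  }
  run_acc <- vapply(seq_len(n), function(i)
    mean(correct[max(1, i - window + 1):i]), numeric(1))
  data.frame(sample = seq_len(n), running_accuracy = run_acc)
}

#' Experiment presets
#'
#' Version-controlled recipes for the benchmark experiments, at the
#' episodic protocol's full scale (5-way tasks, K = 50, Q = 10, 20 trials;
#' 600 episodes for rule benchmarks, 500 with a 100-episode burn-in for the
#' layer-assignment sweep). Each preset returns the arguments needed to
#' build a [meta_config()] plus trial metadata; the task source defaults to
#' the calibrated synthetic generator and can be swapped for an IDX-backed
#' dataset.
#'
#' @param name one of `"benchmark-fa"`, `"benchmark-bp"`, `"pool-discovery"`,
#'   `"ehebb"`, `"oja"`, `"bio"`, `"orthonormality"`, `"layer-assignment"`,
#'   `"online-10way"`.
#' @return a list describing the experiment.
#' @export
experiment_preset <- function(name) {
  presets <- list(
    "benchmark-fa" = list(rule = "FA_baseline", feedback_mode = "FA",
                          episodes = 600, l1_lambda = 0),
    "benchmark-bp" = list(rule = "FA_baseline", feedback_mode = "BP",
                          episodes = 600, l1_lambda = 0),
    "pool-discovery" = list(rule = "pool", feedback_mode = "FA",
                            episodes = 600, l1_lambda = 1e-3),
    "ehebb" = list(rule = "eHebb", feedback_mode = "FA",
                   episodes = 600, l1_lambda = 0),
    "oja" = list(rule = "Oja", feedback_mode = "FA",
                 episodes = 600, l1_lambda = 0),
    "bio" = list(rule = "bio", feedback_mode = "FA",
                 episodes = 600, l1_lambda = 0),
    "orthonormality" = list(rule = "Oja", feedback_mode = "FA",
                            episodes = 600, l1_lambda = 0,
                            track = "ew"),
    "layer-assignment" = list(kind = "layer-assignment",
                              layer_sizes = c(784, 130, 70, 47),
                              episodes = 500, burn_in = 100),
    "online-10way" = list(kind = "online", rule = "bio", M = 10,
                          n_samples = 1000)
  )
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  utils::modifyList(
    list(name = name,
         layer_sizes = c(784, 170, 130, 100, 70, 47),
         M = 5, K = 50, Q = 10, n_trials = 20,
         meta_learning_rate = 1e-3),
    presets[[name]])
}

#' Plot mean +/- bootstrap band of a metric over episodes
#'
#' @param ts a `trial_set`.
#' @param metric history column.
#' @inheritParams bootstrap_ci
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_meta_history <- function(ts, metric = "meta_accuracy", level = 0.98,
                              n_boot = 500) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_meta_history requires ggplot2")
  agg <- aggregate_episodes(ts, metric, level, n_boot)
  ggplot2::ggplot(agg, ggplot2::aes(x = episode, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "episode", y = metric)
}

utils::globalVariables(c("episode", "lower", "upper"))
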