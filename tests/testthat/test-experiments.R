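test_that("global magnitude pruning zeroes the smallest weights", {
  w <- list(c(0.1, -0.5, 0.3, 0.05))
  expect_equal(prune_magnitude(w, 0.5)[[1]], c(0, -0.5, 0.3, 0))
  expect_equal(prune_magnitude(w, 0)[[1]], w[[1]])
  expect_equal(prune_magnitude(w, 1)[[1]], rep(0, 4))
  # ranking is global across arrays, not per array
  w2 <- list(a = c(10, 20), b = c(0.1, 0.2))
  p2 <- prune_magnitude(w2, 0.5)
  expect_equal(p2$a, c(10, 20))
  expect_equal(p2$b, c(0, 0))
})

test_that("sparsity_of counts exact zeros and matches requested levels", {
  expect_equal(sparsity_of(list(c(0, 0, 1, 2))), 0.5)
  w <- withr::with_seed(23, list(matrix(rnorm(40), 5, 8), rnorm(17)))
  n <- 57
  for (s in c(0, 0.25, 0.5, 0.8, 1)) {
    p <- prune_magnitude(w, s)
    expect_lte(abs(sparsity_of(p) - s), 1 / n)
  }
})

test_that("pruning is idempotent and zero sets nest across levels", {
  w <- withr::with_seed(29, list(matrix(rnorm(30), 6, 5), rnorm(11)))
  p5 <- prune_magnitude(w, 0.5)
  expect_identical(prune_magnitude(p5, 0.5), p5)
  zero_set <- function(x) which(unlist(x) == 0)
  prev <- integer(0)
  for (s in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- zero_set(prune_magnitude(w, s))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("grid search enumerates the full Cartesian product deterministically", {
  b <- gen_activations(40, c(3, 4), seed = 61)
  gt <- make_ground_truth("linear", c(3, 4), n_sites = 2, seed = 62)
  rec <- gen_recordings(b, gt, noise_model(sd = 0.1, seed = 63))
  sp <- split_rows(40, 0.8, seed = 64)
  cfg <- train_config(sp, batch_size = 16, max_epochs = 8, patience = 7,
                      seed = 65)
  grid <- grid_spec(list("layer1", c("layer1", "layer2")),
                    l1_sizes = c(2, 3), l2_sizes = 4,
                    learning_rates = c(1e-2, 1e-3), seeds = c(1, 2))
  res <- grid_search(grid, b, rec, cfg)
  expect_equal(nrow(res$table), 2 * 2 * 1 * 2)
  expect_false(any(res$table$failed))
  expect_equal(res$best_config$val_mae, min(res$table$val_mae))
  res2 <- grid_search(grid, b, rec, cfg)
  expect_identical(res$table, res2$table)
})

test_that("a singleton grid returns its only cell as best", {
  b <- gen_activations(30, c(3), seed = 71)
  gt <- make_ground_truth("linear", c(3), n_sites = 2, seed = 72)
  rec <- gen_recordings(b, gt, noise_model(sd = 0.1, seed = 73))
  cfg <- train_config(split_rows(30, 0.8, seed = 74), batch_size = 8,
                      max_epochs = 5, patience = 4, seed = 75)
  grid <- grid_spec(list("layer1"), 2, 3, 1e-3, seeds = 1)
  res <- grid_search(grid, b, rec, cfg)
  expect_equal(nrow(res$table), 1)
  expect_equal(res$best_config$cell, 1)
  expect_identical(res$best_config$layers, "layer1")
})

test_that("the reference base network trains and exposes hidden activations", {
  task <- gen_base_task(300, d = 8, n_classes = 3, seed = 81)
  net <- make_base_network(8, c(16, 12), n_classes = 3, seed = 82)
  net <- train_base_network(net, task$X, task$y, epochs = 120)
  expect_gt(net$accuracy, 0.85)
  bundle <- extract_activations(net, task$X, task$stimulus_ids)
  expect_identical(bundle$layer_names, c("h1", "h2"))
  expect_identical(dim(bundle$matrices$h1), c(300L, 16L))
  expect_true(all(bundle$matrices$h1 >= 0))   # post-ReLU
})

test_that("the pruning sweep mechanics hold on the packaged fixture", {
  task <- gen_base_task(250, d = 8, n_classes = 3, seed = 91)
  net <- make_base_network(8, c(12, 10), n_classes = 3, seed = 92)
  net <- train_base_network(net, task$X, task$y, epochs = 100)
  bundle0 <- extract_activations(net, task$X, task$stimulus_ids)
  gt <- make_ground_truth("mlp", c(12, 10), n_sites = 6, hidden_width = 16,
                          seed = 93)
  rec <- gen_recordings(bundle0, gt, noise_model(sd = 0.05, seed = 94))
  sp <- split_rows(250, 0.8, seed = 95)
  spec <- nrp_spec(c("h1", "h2"), l1_units = 8, l2_units = 12,
                   n_outputs = 6, init_seed = 96)
  cfg <- train_config(sp, learning_rate = 3e-3, batch_size = 32,
                      max_epochs = 40, patience = 39, seed = 97)
  levels <- c(0, 0.2, 0.4, 0.6, 0.8)
  rep <- pruning_sweep(net, task$X, rec, levels, spec, cfg)
  expect_equal(rep$sparsity_levels, levels)
  expect_length(rep$nrp_errors, 5)
  expect_true(all(is.finite(rep$nrp_errors)))
  n_w <- length(unlist(nrpredict:::base_weights(net)))
  expect_true(all(abs(rep$achieved_sparsity - levels) <= 1 / n_w))

  # a sweep at level 0 alone reproduces the unpruned pipeline's error
  rep0 <- pruning_sweep(net, task$X, rec, 0, spec, cfg)
  model <- build_nrp(spec, c(h1 = 12L, h2 = 10L))
  fit <- train_nrp(model, bundle0, rec, cfg)
  direct <- nrp_error_by_region(predict(fit, bundle0), rec,
                                rows = sp$val_rows)
  expect_equal(rep0$nrp_errors[1], direct$overall_error, tolerance = 1e-12)
  # sweep is reproducible end to end
  rep0b <- pruning_sweep(net, task$X, rec, 0, spec, cfg)
  expect_identical(rep0, rep0b)
})

test_that("the nonlinear-vs-linear comparison is a deterministic paired run", {
  b <- gen_activations(120, c(6, 5), seed = 55)
  gt <- make_ground_truth("linear", c(6, 5), n_sites = 4, seed = 56)
  rec <- gen_recordings(b, gt, noise_model(sd = 0, seed = 57))
  sp <- split_rows(120, 0.8, seed = 58)
  spec <- nrp_spec(c("layer1", "layer2"), l1_units = 6, l2_units = 8,
                   n_outputs = 4, init_seed = 59)
  cfg <- train_config(sp, learning_rate = 1e-2, batch_size = 32,
                      max_epochs = 600, patience = 599, seed = 60,
                      lr_schedule = "cosine", n_restarts = 2)
  cmp1 <- compare_nonlinear_vs_linear(b, rec, spec, cfg, ridge_lambda = 0)
  cmp2 <- compare_nonlinear_vs_linear(b, rec, spec, cfg, ridge_lambda = 0)
  expect_identical(cmp1, cmp2)
  # on a noise-free linear truth both families represent the target: the
  # closed-form baseline recovers it exactly, and the trained decoder gets
  # close on the unit response scale rather than dominating either way
  expect_lt(cmp1$linear$overall_error, 1e-6)
  expect_lt(cmp1$nonlinear$overall_error, 0.1)
  expect_gt(cmp1$ratio, 1)
})
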