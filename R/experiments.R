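#' Hyperparameter grid for the decoder architecture search
#'
#' Recording datasets are small (a few thousand stimuli), so the decoder must
#' balance capacity against trainability; the grid search explores (i) which
#' ANN layers feed the decoder, (ii) the sizes of its two intermediate
#' layers, and (iii) the learning rate. Cells are enumerated in a fixed
#' deterministic order: layer subsets vary slowest, then L1 size, L2 size,
#' learning rate.
#'
#' @param layer_subsets list of character vectors, each a subset of bundle
#'   layer names to feed the decoder.
#' @param l1_sizes integer vector of per-block L1 widths to try.
#' @param l2_sizes integer vector of L2 widths to try.
#' @param learning_rates numeric vector of Adam step sizes to try.
#' @param seeds integer vector; each cell is trained once per seed and its
#'   validation MAEs averaged.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(layer_subsets, l1_sizes, l2_sizes,
                      learning_rates, seeds = 1L) {
  if (is.character(layer_subsets)) layer_subsets <- list(layer_subsets)
  assert_that(length(layer_subsets) >= 1L && length(l1_sizes) >= 1L &&
                length(l2_sizes) >= 1L && length(learning_rates) >= 1L &&
                length(seeds) >= 1L,
              "all grid axes must be nonempty")
  structure(list(layer_subsets = layer_subsets,
                 l1_sizes = as.integer(l1_sizes),
                 l2_sizes = as.integer(l2_sizes),
                 learning_rates = as.numeric(learning_rates),
                 seeds = as.integer(seeds)),
            class = "grid_spec")
}

#' Grid search over decoder architectures
#'
#' Trains one decoder per grid cell and seed (fresh initialization, shared
#' data split), averages each cell's validation MAE over the seeds, and
#' selects the cell with the lowest average (ties broken by enumeration
#' order). A cell whose training aborts is marked failed and excluded from
#' the argmin; the search continues.
#'
#' @param grid a [grid_spec()].
#' @param bundle an [activation_bundle()], row-aligned with `recordings`.
#' @param recordings a [recording_set()].
#' @param cfg_template a [train_config()]; its split, batch size, epoch
#'   budget, patience and seed are reused for every cell, with the learning
#'   rate and init seed overridden per cell.
#' @return an object of class `search_result`: `table` (one data-frame row
#'   per cell with config, mean validation MAE, mean best epoch, `failed`)
#'   and `best_config` (list with the winning cell's settings).
#' @export
grid_search <- function(grid, bundle, recordings, cfg_template) {
  stopifnot(inherits(grid, "grid_spec"),
            inherits(cfg_template, "train_config"))
  input_dims <- vapply(bundle$matrices, ncol, 0L)
  rows <- list()
  cell <- 0L
  for (subset_i in seq_along(grid$layer_subsets)) {
    layers <- grid$layer_subsets[[subset_i]]
    for (l1 in grid$l1_sizes) for (l2 in grid$l2_sizes)
      for (lr in grid$learning_rates) {
        cell <- cell + 1L
        maes <- numeric(0)
        epochs <- numeric(0)
        failed <- FALSE
        for (sd in grid$seeds) {
          res <- tryCatch({
            spec <- nrp_spec(layers, l1_units = l1, l2_units = l2,
                             n_outputs = ncol(recordings$responses),
                             init_seed = sd)
            model <- build_nrp(spec, input_dims)
            cfg <- train_config(cfg_template$split, learning_rate = lr,
                                batch_size = cfg_template$batch_size,
                                max_epochs = cfg_template$max_epochs,
                                patience = cfg_template$patience,
                                seed = derive_seed(cfg_template$seed, sd))
            train_nrp(model, bundle, recordings, cfg)
          }, error = function(e) NULL)
          if (is.null(res)) { failed <- TRUE; break }
          maes <- c(maes, res$best_val_mae)
          epochs <- c(epochs, res$best_epoch)
        }
        rows[[cell]] <- data.frame(
          cell = cell,
          layers = paste(layers, collapse = "+"),
          l1_units = l1, l2_units = l2, learning_rate = lr,
          val_mae = if (failed) NA_real_ else mean(maes),
          best_epoch = if (failed) NA_real_ else mean(epochs),
          failed = failed)
      }
  }
  table <- do.call(rbind, rows)
  ok <- which(!table$failed)
  assert_that(length(ok) > 0L, "every grid cell failed to train")
  best_i <- ok[which.min(table$val_mae[ok])]
  best <- table[best_i, ]
  structure(list(
    table = table,
    best_config = list(cell = best$cell,
                       layers = strsplit(best$layers, "+", fixed = TRUE)[[1]],
                       l1_units = best$l1_units, l2_units = best$l2_units,
                       learning_rate = best$learning_rate,
                       val_mae = best$val_mae)),
    class = "search_result")
}

#' Global magnitude pruning
#'
#' Ranks all weight entries across the supplied arrays by absolute value and
#' zeroes the smallest `floor(sparsity * n)` of them; surviving weights are
#' unchanged and biases are never included. Ties are broken by position
#' (stable), so zero sets are nested across increasing sparsity levels. This
#' is a one-shot global scheme with no fine-tuning.
#'
#' @param weights list of numeric arrays (weight matrices only).
#' @param sparsity fraction of entries to zero, in `[0, 1]`.
#' @return the list with the selected entries set to exactly zero.
#' @export
prune_magnitude <- function(weights, sparsity) {
  assert_that(is.numeric(sparsity) && length(sparsity) == 1L &&
                sparsity >= 0 && sparsity <= 1,
              "sparsity must lie in [0, 1]")
  if (!is.list(weights)) weights <- list(weights)
  flat <- abs(unlist(weights, use.names = FALSE))
  k <- floor(sparsity * length(flat))
  if (k == 0L) return(weights)
  kill <- order(flat)[seq_len(k)]
  offset <- 0L
  for (i in seq_along(weights)) {
    n_i <- length(weights[[i]])
    local <- kill[kill > offset & kill <= offset + n_i] - offset
    if (length(local)) weights[[i]][local] <- 0
    offset <- offset + n_i
  }
  weights
}

#' Fraction of exactly-zero weights
#'
#' @param weights list of numeric arrays (biases excluded by convention).
#' @return scalar sparsity in `[0, 1]`.
#' @export
sparsity_of <- function(weights) {
  if (!is.list(weights)) weights <- list(weights)
  flat <- unlist(weights, use.names = FALSE)
  assert_that(length(flat) > 0L, "sparsity_of needs a nonempty collection")
  mean(flat == 0)
}

#' Pruning-sensitivity sweep
#'
#' For each sparsity level: prune the base network's weights globally by
#' magnitude, re-extract its hidden activations on the stimulus set, train a
#' fresh decoder under the identical protocol (same split, seeds and
#' architecture), and record the overall held-out NRP-error. This measures
#' how compressing the base network changes how predictable the recordings
#' are from its activations.
#'
#' @param base_net a trained [make_base_network()] network.
#' @param X stimulus matrix fed to the base network.
#' @param recordings a [recording_set()] for the same stimuli.
#' @param levels strictly increasing sparsity levels in `[0, 1]`.
#' @param spec_template an [nrp_spec()] (its `source_layers` must be
#'   `c("h1", "h2")` or a subset).
#' @param cfg a [train_config()].
#' @return an object of class `prune_report`: `sparsity_levels`,
#'   `nrp_errors` (overall held-out NRP-error per level), `achieved_sparsity`
#'   and `base_model_descriptor`.
#' @export
pruning_sweep <- function(base_net, X, recordings, levels, spec_template,
                          cfg) {
  stopifnot(inherits(base_net, "base_network"),
            inherits(spec_template, "nrp_spec"),
            inherits(cfg, "train_config"))
  levels <- as.numeric(levels)
  assert_that(all(levels >= 0 & levels <= 1),
              "sparsity levels must lie in [0, 1]")
  assert_that(all(diff(levels) > 0) || length(levels) == 1L,
              "sparsity levels must be strictly increasing")
  W0 <- base_weights(base_net)
  errs <- numeric(length(levels))
  achieved <- numeric(length(levels))
  for (i in seq_along(levels)) {
    Wp <- prune_magnitude(W0, levels[i])
    achieved[i] <- sparsity_of(Wp)
    net_p <- set_base_weights(base_net, Wp)
    bundle <- extract_activations(net_p, X, recordings$stimulus_ids)
    input_dims <- vapply(bundle$matrices, ncol, 0L)
    model <- build_nrp(spec_template, input_dims)
    fit <- train_nrp(model, bundle, recordings, cfg)
    pred <- predict(fit, bundle)
    rep <- nrp_error_by_region(pred, recordings, rows = cfg$split$val_rows,
                               model_descriptor = sprintf(
                                 "base network at sparsity %.2f", levels[i]))
    errs[i] <- rep$overall_error
  }
  structure(list(sparsity_levels = levels, nrp_errors = errs,
                 achieved_sparsity = achieved,
                 base_model_descriptor = sprintf(
                   "3-layer reference MLP (%s)",
                   paste(base_net$dims, collapse = "-"))),
            class = "prune_report")
}

#' Head-to-head comparison of the nonlinear decoder and the linear baseline
#'
#' Trains the decoder and fits the linear baseline on the identical split and
#' data, scores both on the held-out rows per region, and reports the ratio
#' of overall errors (nonlinear / linear; values below 1 mean the nonlinear
#' decoder predicts the recordings better).
#'
#' @param bundle an [activation_bundle()], row-aligned with `recordings`.
#' @param recordings a [recording_set()].
#' @param spec an [nrp_spec()].
#' @param cfg a [train_config()] (its split is shared with the baseline).
#' @param ridge_lambda passed to [fit_linear()].
#' @return list with `nonlinear` and `linear` (both `nrp_report`s on the
#'   validation rows), `ratio`, and `linear_r2` (held-out mean R-squared of
#'   the baseline).
#' @export
compare_nonlinear_vs_linear <- function(bundle, recordings, spec, cfg,
                                        ridge_lambda = NULL) {
  input_dims <- vapply(bundle$matrices, ncol, 0L)
  model <- build_nrp(spec, input_dims)
  fit <- train_nrp(model, bundle, recordings, cfg)
  va <- cfg$split$val_rows
  rep_nl <- nrp_error_by_region(predict(fit, bundle), recordings, rows = va,
                                model_descriptor = "nonlinear decoder")
  lin <- fit_linear(bundle, recordings, cfg$split, ridge_lambda)
  rep_li <- nrp_error_by_region(predict_linear(lin, bundle), recordings,
                                rows = va,
                                model_descriptor = "linear baseline")
  r2 <- r_squared(lin, bundle, recordings, rows = va)
  list(nonlinear = rep_nl, linear = rep_li,
       ratio = rep_nl$overall_error / rep_li$overall_error,
       linear_r2 = r2$mean)
}
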