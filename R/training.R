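#' Training configuration for the decoder
#'
#' The decoder is fit by minimizing the mean squared error between predicted
#' and measured normalized firing rates with Adam updates over mini-batches.
#' The reported metric is different: validation mean absolute error, the same
#' quantity the NRP-error uses, is scored every epoch, drives early stopping,
#' and selects the weights that are kept.
#'
#' @param split a [split_rows()] index defining train and validation rows.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs epoch budget (default 500).
#' @param patience epochs without validation improvement before stopping
#'   (default 20); must be smaller than `max_epochs`.
#' @param seed integer seed controlling mini-batch shuffling.
#' @param lr_schedule `"constant"` (default) keeps the step size fixed;
#'   `"cosine"` anneals it from `learning_rate` down to 0.1% of it over
#'   `max_epochs`, which tightens the final fit on noise-free targets.
#' @param n_restarts number of independent seeded initializations to train;
#'   the restart with the lowest validation MAE is kept (default 1). Small
#'   decoders can land in poor local minima, and multi-restart selection on
#'   the validation split is the standard remedy.
#' @return an object of class `train_config`.
#' @export
train_config <- function(split, learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 500L, patience = 20L, seed = 1L,
                         lr_schedule = c("constant", "cosine"),
                         n_restarts = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  assert_that(is_count(n_restarts), "n_restarts must be a positive integer")
  stopifnot(inherits(split, "split_index"))
  assert_that(is.numeric(learning_rate) && learning_rate > 0,
              "learning_rate must be positive")
  assert_that(is_count(batch_size) && is_count(max_epochs),
              "batch_size and max_epochs must be positive integers")
  assert_that(patience >= 0 && patience < max_epochs,
              "patience must satisfy 0 <= patience < max_epochs")
  structure(list(split = split, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 lr_schedule = lr_schedule,
                 n_restarts = as.integer(n_restarts)),
            class = "train_config")
}

# Flatten model parameters into a named list of arrays (order matters and is
# shared with gradients and Adam moment estimates).
model_params <- function(model) {
  p <- list()
  for (i in seq_along(model$blocks)) {
    p[[paste0("W1.", i)]] <- model$blocks[[i]]$W
    p[[paste0("b1.", i)]] <- model$blocks[[i]]$b
  }
  p$W2 <- model$W2; p$b2 <- model$b2
  p$Wout <- model$Wout; p$bout <- model$bout
  p
}

set_model_params <- function(model, p) {
  for (i in seq_along(model$blocks)) {
    model$blocks[[i]]$W <- p[[paste0("W1.", i)]]
    model$blocks[[i]]$b <- p[[paste0("b1.", i)]]
  }
  model$W2 <- p$W2; model$b2 <- p$b2
  model$Wout <- p$Wout; model$bout <- p$bout
  model
}

# Backpropagate the MSE loss through the decoder for one batch.
# Returns list(loss, grads) with grads matching model_params() layout.
nrp_grads <- function(model, xs, y) {
  cache <- nrp_forward_cached(model, xs)
  n_entries <- length(y)
  resid <- cache$out - y
  loss <- sum(resid^2) / n_entries
  dOut <- 2 * resid / n_entries
  g <- list()
  g$Wout <- crossprod(cache$H2, dOut)
  g$bout <- colSums(dOut)
  dH2 <- dOut %*% t(model$Wout)
  dZ2 <- dH2 * (cache$Z2 > 0)
  g$W2 <- crossprod(cache$H1cat, dZ2)
  g$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(model$W2)
  col0 <- 0L
  for (i in seq_along(xs)) {
    u <- ncol(model$blocks[[i]]$W)
    dZ1 <- dH1[, col0 + seq_len(u), drop = FALSE] * (cache$Z1[[i]] > 0)
    g[[paste0("W1.", i)]] <- crossprod(xs[[i]], dZ1)
    g[[paste0("b1.", i)]] <- colSums(dZ1)
    col0 <- col0 + u
  }
  list(loss = loss, grads = g)
}

#' Fit the decoder to neural recordings
#'
#' Optimizes MSE on the training rows with Adam; after every epoch the
#' decoder is scored on the validation rows by mean absolute error. The
#' weights from the epoch with the lowest validation MAE are restored at the
#' end (ties go to the earliest epoch), and training stops early once
#' `patience` epochs pass without improvement. The run is fully deterministic
#' given the split seed, the model's `init_seed`, and `cfg$seed`.
#'
#' @param model a freshly built `nrp_model` (see [build_nrp()]).
#' @param bundle an [activation_bundle()], row-aligned with `recordings`.
#' @param recordings a [recording_set()]; its site count must equal the
#'   model's `n_outputs`.
#' @param cfg a [train_config()].
#' @return an object of class `nrp_train_result` with fields `model`
#'   (best-validation weights), `history` (data frame of per-epoch train loss
#'   and validation MAE, for the winning restart), `best_epoch`, and
#'   `best_val_mae`.
#' @export
train_nrp <- function(model, bundle, recordings, cfg) {
  stopifnot(inherits(model, "nrp_model"), inherits(cfg, "train_config"))
  if (cfg$n_restarts == 1L)
    return(train_nrp_once(model, bundle, recordings, cfg))
  input_dims <- vapply(model$blocks, function(b) nrow(b$W), 0L)
  names(input_dims) <- model$spec$source_layers
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    m_r <- if (r == 1L) model else {
      spec_r <- model$spec
      spec_r$init_seed <- derive_seed(model$spec$init_seed, r)
      build_nrp(spec_r, input_dims)
    }
    cfg_r <- cfg
    cfg_r$n_restarts <- 1L
    if (r > 1L) cfg_r$seed <- derive_seed(cfg$seed, r - 1L)
    res <- train_nrp_once(m_r, bundle, recordings, cfg_r)
    if (is.null(best) || res$best_val_mae < best$best_val_mae) best <- res
  }
  best$config <- cfg
  best
}

train_nrp_once <- function(model, bundle, recordings, cfg) {
  stopifnot(inherits(model, "nrp_model"),
            inherits(bundle, "activation_bundle"),
            inherits(recordings, "recording_set"),
            inherits(cfg, "train_config"))
  assert_that(identical(bundle$stimulus_ids, recordings$stimulus_ids),
              "bundle and recordings must be aligned (same stimuli, same order)")
  assert_that(model$spec$n_outputs == ncol(recordings$responses),
              "model n_outputs must equal the recording site count")
  xs_all <- extract_inputs(model, bundle)
  y_all <- recordings$responses
  tr <- cfg$split$train_rows
  va <- cfg$split$val_rows
  assert_that(max(tr, va) <= nrow(y_all),
              "split indices exceed the number of aligned stimuli")
  xs_tr <- lapply(xs_all, function(m) m[tr, , drop = FALSE])
  xs_va <- lapply(xs_all, function(m) m[va, , drop = FALSE])
  y_tr <- y_all[tr, , drop = FALSE]
  y_va <- y_all[va, , drop = FALSE]
  n_tr <- length(tr)

  params <- model_params(model)
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  hist_loss <- numeric(0)
  hist_val <- numeric(0)

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- if (cfg$lr_schedule == "cosine") {
        frac <- (epoch - 1) / max(1L, cfg$max_epochs - 1L)
        cfg$learning_rate * (0.001 + 0.999 * 0.5 * (1 + cos(pi * frac)))
      } else cfg$learning_rate
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
        xb <- lapply(xs_tr, function(m) m[idx, , drop = FALSE])
        yb <- y_tr[idx, , drop = FALSE]
        gl <- nrp_grads(model, xb, yb)
        if (!is.finite(gl$loss))
          stop(sprintf(paste0("training aborted: non-finite loss at epoch %d ",
                              "(learning rate too large?)"), epoch),
               call. = FALSE)
        epoch_loss <- epoch_loss + gl$loss * length(idx)
        t_step <- t_step + 1L
        corr <- lr * sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
        for (nm in names(params)) {
          gcur <- gl$grads[[nm]]
          m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * gcur
          m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * gcur^2
          params[[nm]] <- params[[nm]] - corr * m1[[nm]] /
            (sqrt(m2[[nm]]) + eps)
        }
        model <- set_model_params(model, params)
      }
      val_pred <- nrp_forward_cached(model, xs_va)$out
      val_mae <- mean(abs(val_pred - y_va))
      hist_loss <- c(hist_loss, epoch_loss / n_tr)
      hist_val <- c(hist_val, val_mae)
      if (val_mae < best_val) {
        best_val <- val_mae
        best_params <- params
        best_epoch <- epoch
      } else if (epoch - best_epoch > cfg$patience) {
        break
      }
    }
  })

  model <- set_model_params(model, best_params)
  structure(list(model = model,
                 history = data.frame(epoch = seq_along(hist_loss),
                                      train_loss = hist_loss,
                                      val_mae = hist_val),
                 best_epoch = best_epoch,
                 best_val_mae = best_val,
                 config = cfg),
            class = "nrp_train_result")
}

#' @export
print.nrp_train_result <- function(x, ...) {
  cat(sprintf(paste0("<nrp_train_result> %d epoch(s); best epoch %d, ",
                     "validation MAE %.5f\n"),
              nrow(x$history), x$best_epoch, x$best_val_mae))
  invisible(x)
}

#' Predict neural responses with a trained decoder
#'
#' @param object an `nrp_train_result` from [train_nrp()].
#' @param bundle an [activation_bundle()] containing the model's source
#'   layers (any stimuli, including none).
#' @param ... unused.
#' @return numeric matrix `[n_stimuli, n_outputs]` of predicted normalized
#'   firing rates, from the best-validation weights.
#' @export
predict.nrp_train_result <- function(object, bundle, ...) {
  nrp_forward(object$model, bundle)
}
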