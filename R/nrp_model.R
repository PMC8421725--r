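#' Architecture specification for the neural response decoder
#'
#' The decoder maps ANN layer activations to predicted normalized firing
#' rates through exactly two intermediate layers. The first (L1) is *locally
#' dense*: each source layer's activations feed only its own block of units,
#' with no cross-layer weights, which keeps the parameter count small. Block
#' outputs are concatenated and passed through a dense second layer (L2).
#' ReLU follows both L1 and L2; the output layer is linear and has one unit
#' per recording site, so predicted rates may take any real value (a response
#' below the blank-gray baseline is representable).
#'
#' @param source_layers character vector naming the activation-bundle layers
#'   fed to the decoder, in block order.
#' @param l1_units integer vector, units per L1 block (recycled if length 1).
#' @param l2_units integer, units in the dense L2 layer.
#' @param n_outputs integer, number of recording sites to predict.
#' @param init_seed integer seed for weight initialization.
#' @return an object of class `nrp_spec`.
#' @export
nrp_spec <- function(source_layers, l1_units = 64L, l2_units = 128L,
                     n_outputs, init_seed = 1L) {
  source_layers <- as.character(source_layers)
  assert_that(length(source_layers) >= 1L &&
                anyDuplicated(source_layers) == 0L,
              "source_layers must be a nonempty set of distinct layer names")
  l1_units <- as.integer(l1_units)
  if (length(l1_units) == 1L)
    l1_units <- rep(l1_units, length(source_layers))
  assert_that(length(l1_units) == length(source_layers),
              "l1_units must have one entry per source layer")
  assert_that(all(l1_units >= 1L) && is_count(l2_units) && is_count(n_outputs),
              "layer sizes must be positive integers")
  structure(list(source_layers = source_layers, l1_units = l1_units,
                 l2_units = as.integer(l2_units),
                 n_outputs = as.integer(n_outputs),
                 init_seed = as.integer(init_seed)),
            class = "nrp_spec")
}

#' Instantiate decoder weights for a given architecture
#'
#' Weights are drawn with a seeded fan-in-scaled Gaussian scheme: hidden
#' layers use sd `sqrt(2 / fan_in)` (matched to ReLU), the linear output
#' layer uses sd `sqrt(1 / fan_in)`; biases start at zero. Construction is
#' fully deterministic in `spec$init_seed`.
#'
#' @param spec an [nrp_spec()].
#' @param input_dims named integer vector of activation dimensions, one per
#'   source layer (names must cover `spec$source_layers`).
#' @return an object of class `nrp_model` holding per-block L1 weights, the
#'   dense L2 weights, and the output weights.
#' @export
build_nrp <- function(spec, input_dims) {
  stopifnot(inherits(spec, "nrp_spec"))
  assert_that(!is.null(names(input_dims)) &&
                all(spec$source_layers %in% names(input_dims)),
              "input_dims must be named and cover every source layer")
  dims <- as.integer(input_dims[spec$source_layers])
  assert_that(all(dims >= 1L), "every source layer must have >= 1 units")
  withr::with_seed(spec$init_seed, {
    blocks <- vector("list", length(dims))
    for (i in seq_along(dims)) {
      u <- spec$l1_units[i]
      blocks[[i]] <- list(
        W = matrix(stats::rnorm(dims[i] * u, sd = sqrt(2 / dims[i])),
                   dims[i], u),
        b = numeric(u))
    }
    names(blocks) <- spec$source_layers
    h <- sum(spec$l1_units)
    W2 <- matrix(stats::rnorm(h * spec$l2_units, sd = sqrt(2 / h)),
                 h, spec$l2_units)
    Wout <- matrix(stats::rnorm(spec$l2_units * spec$n_outputs,
                                sd = sqrt(1 / spec$l2_units)),
                   spec$l2_units, spec$n_outputs)
    structure(list(spec = spec, blocks = blocks,
                   W2 = W2, b2 = numeric(spec$l2_units),
                   Wout = Wout, bout = numeric(spec$n_outputs)),
              class = "nrp_model")
  })
}

#' @export
print.nrp_model <- function(x, ...) {
  cat(sprintf(paste0("<nrp_model> %d locally dense block(s) [%s] -> L2 %d ",
                     "-> %d site(s); %d parameters\n"),
              length(x$blocks),
              paste(x$spec$l1_units, collapse = ","),
              x$spec$l2_units, x$spec$n_outputs,
              n_model_params(x)))
  invisible(x)
}

# Forward pass with intermediate caches (for backprop).
nrp_forward_cached <- function(model, xs) {
  Z1 <- vector("list", length(xs))
  H1 <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    Z1[[i]] <- sweep(xs[[i]] %*% model$blocks[[i]]$W, 2,
                     model$blocks[[i]]$b, "+")
    H1[[i]] <- relu(Z1[[i]])
  }
  H1cat <- do.call(cbind, H1)
  Z2 <- sweep(H1cat %*% model$W2, 2, model$b2, "+")
  H2 <- relu(Z2)
  out <- sweep(H2 %*% model$Wout, 2, model$bout, "+")
  list(Z1 = Z1, H1cat = H1cat, Z2 = Z2, H2 = H2, out = out)
}

#' Run the decoder on an activation bundle
#'
#' Computes, per stimulus, `h1_i = ReLU(x_i W1_i + b1_i)` for each locally
#' dense block, `h2 = ReLU(concat(h1) W2 + b2)`, and the linear output
#' `h2 Wout + bout` — the predicted normalized firing rates.
#'
#' @param model an `nrp_model`.
#' @param bundle an [activation_bundle()] containing all source layers with
#'   matching dimensions.
#' @return numeric matrix `[n_stimuli, n_outputs]` of predicted rates.
#' @export
nrp_forward <- function(model, bundle) {
  stopifnot(inherits(model, "nrp_model"),
            inherits(bundle, "activation_bundle"))
  xs <- extract_inputs(model, bundle)
  nrp_forward_cached(model, xs)$out
}

# Pull out (and dimension-check) the source-layer matrices, in block order.
extract_inputs <- function(model, bundle) {
  missing <- setdiff(model$spec$source_layers, bundle$layer_names)
  if (length(missing) > 0L)
    stop(sprintf("bundle is missing source layer(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  xs <- lapply(model$spec$source_layers, function(nm) bundle$matrices[[nm]])
  for (i in seq_along(xs)) {
    expected <- nrow(model$blocks[[i]]$W)
    assert_that(ncol(xs[[i]]) == expected,
                sprintf("layer '%s' has %d units, model expects %d",
                        model$spec$source_layers[i], ncol(xs[[i]]), expected))
  }
  xs
}

#' Trainable parameter count of a decoder architecture
#'
#' Computes `sum_i (d_i u_i + u_i) + (sum_i u_i) l2 + l2 + l2 n_out + n_out`,
#' the number of trainable scalars implied by the locally dense structure.
#' Local density is what keeps this small: a fully dense first layer over the
#' concatenated activations would couple every input to every L1 unit.
#'
#' @param spec an [nrp_spec()].
#' @param input_dims named integer vector of per-layer activation dimensions.
#' @return integer parameter count.
#' @export
param_count <- function(spec, input_dims) {
  stopifnot(inherits(spec, "nrp_spec"))
  dims <- as.integer(input_dims[spec$source_layers])
  u <- spec$l1_units
  sum(dims * u + u) + sum(u) * spec$l2_units + spec$l2_units +
    spec$l2_units * spec$n_outputs + spec$n_outputs
}

# Count of scalars actually present in a built model.
n_model_params <- function(model) {
  sum(vapply(model$blocks, function(b) length(b$W) + length(b$b), 0)) +
    length(model$W2) + length(model$b2) +
    length(model$Wout) + length(model$bout)
}
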