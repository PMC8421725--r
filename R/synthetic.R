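#' Generate a synthetic activation bundle
#'
#' Rows are i.i.d. standard Gaussian per layer — a controlled stand-in for
#' real ANN activations that keeps the activation-to-response map fully
#' known. Stimulus IDs are `"s0000"`, `"s0001"`, ... and the draw is
#' deterministic in the seed.
#'
#' @param n_stimuli number of stimuli (rows).
#' @param layer_dims integer vector of per-layer activation dimensions;
#'   layers are named `"layer1"`, `"layer2"`, ...
#' @param seed integer seed.
#' @return an [activation_bundle()].
#' @export
gen_activations <- function(n_stimuli, layer_dims, seed) {
  assert_that(is_count(n_stimuli), "n_stimuli must be a positive integer")
  layer_dims <- as.integer(layer_dims)
  assert_that(length(layer_dims) >= 1L && all(layer_dims >= 1L),
              "layer_dims must be positive integers")
  ids <- sprintf("s%04d", seq_len(n_stimuli) - 1L)
  mats <- withr::with_seed(as.integer(seed),
    lapply(layer_dims, function(d)
      matrix(stats::rnorm(n_stimuli * d), n_stimuli, d)))
  names(mats) <- paste0("layer", seq_along(layer_dims))
  activation_bundle(mats, ids)
}

#' Construct a known ground-truth activation-to-response map
#'
#' The generator's truth stands in for the unknown brain transformation: a
#' `linear` map (affine in the concatenated activations) that a linear
#' regression can recover exactly, or an `mlp` map (concatenated activations
#' -> ReLU hidden layer -> linear readout) that lies outside the linear
#' family, so a linear fit provably leaves residual variance behind.
#' Parameters are seeded Gaussians, then output columns are rescaled so each
#' site's response standard deviation is approximately 1 over a reference
#' Gaussian stimulus draw — keeping MAE values interpretable as fractions of
#' the response spread. Regeneration with identical arguments reproduces
#' identical parameters.
#'
#' @param kind `"linear"` or `"mlp"`.
#' @param layer_dims integer vector of activation dimensions the map expects.
#' @param n_sites number of recording sites (output columns).
#' @param hidden_width width of the ReLU hidden layer (`mlp` only, >= 1;
#'   default 64).
#' @param seed integer seed.
#' @return an object of class `ground_truth_map`.
#' @export
make_ground_truth <- function(kind = c("linear", "mlp"), layer_dims, n_sites,
                              hidden_width = 64L, seed) {
  kind <- match.arg(kind)
  layer_dims <- as.integer(layer_dims)
  assert_that(all(layer_dims >= 1L) && is_count(n_sites),
              "layer_dims and n_sites must be positive integers")
  D <- sum(layer_dims)
  n_ref <- 2000L
  withr::with_seed(as.integer(seed), {
    Xref <- matrix(stats::rnorm(n_ref * D), n_ref, D)
    if (kind == "linear") {
      W <- matrix(stats::rnorm(D * n_sites), D, n_sites)
      intercept <- stats::rnorm(n_sites, sd = 0.2)
      ref <- Xref %*% W
      sds <- apply(ref, 2, stats::sd)
      W <- sweep(W, 2, sds, "/")
      params <- list(W = W, intercept = intercept)
    } else {
      assert_that(is_count(hidden_width), "hidden_width must be >= 1")
      Wh <- matrix(stats::rnorm(D * hidden_width, sd = sqrt(2 / D)),
                   D, hidden_width)
      bh <- stats::rnorm(hidden_width, sd = 0.5)
      Wo <- matrix(stats::rnorm(hidden_width * n_sites), hidden_width,
                   n_sites)
      intercept <- stats::rnorm(n_sites, sd = 0.2)
      H <- relu(sweep(Xref %*% Wh, 2, bh, "+"))
      ref <- H %*% Wo
      sds <- apply(ref, 2, stats::sd)
      Wo <- sweep(Wo, 2, sds, "/")
      params <- list(Wh = Wh, bh = bh, Wo = Wo, intercept = intercept)
    }
  })
  structure(list(kind = kind, input_dims = layer_dims,
                 n_sites = as.integer(n_sites),
                 hidden_width = if (kind == "mlp") as.integer(hidden_width)
                                else NA_integer_,
                 parameters = params, seed = as.integer(seed)),
            class = "ground_truth_map")
}

#' Apply a ground-truth map to activations
#'
#' @param map a [make_ground_truth()] object.
#' @param bundle an [activation_bundle()] whose per-layer dimensions match
#'   `map$input_dims`.
#' @return numeric matrix `[n_stimuli, n_sites]` of noise-free responses.
#' @export
apply_ground_truth <- function(map, bundle) {
  stopifnot(inherits(map, "ground_truth_map"),
            inherits(bundle, "activation_bundle"))
  dims <- vapply(bundle$matrices, ncol, 0L)
  assert_that(length(dims) == length(map$input_dims) &&
                all(dims == map$input_dims),
              sprintf("bundle dims (%s) do not match map input_dims (%s)",
                      paste(dims, collapse = ","),
                      paste(map$input_dims, collapse = ",")))
  X <- concat_layers(bundle)
  p <- map$parameters
  if (map$kind == "linear") {
    sweep(X %*% p$W, 2, p$intercept, "+")
  } else {
    H <- relu(sweep(X %*% p$Wh, 2, p$bh, "+"))
    sweep(H %*% p$Wo, 2, p$intercept, "+")
  }
}

#' Observation-noise model for synthetic recordings
#'
#' @param sd Gaussian noise standard deviation, in units of the normalized
#'   response (>= 0; `sd = 0` makes recordings an exact function of the
#'   activations). Default 0.1.
#' @param seed integer seed for the noise draw.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.1, seed = 1L) {
  assert_that(is.numeric(sd) && length(sd) == 1L && sd >= 0,
              "sd must be a nonnegative scalar")
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

#' Generate synthetic neural recordings from activations
#'
#' Responses are the ground-truth map applied to the bundle plus elementwise
#' Gaussian noise, with one region label per site. With the default region
#' layout (88 `"V4"` + 168 `"IT"` sites when `n_sites = 256`) the output
#' mirrors the shape of primate ventral-stream recording tables.
#'
#' @param bundle an [activation_bundle()].
#' @param map a [make_ground_truth()] object.
#' @param noise a [noise_model()].
#' @param regions character vector of region labels, one per site.
#' @return a [recording_set()] aligned with `bundle`.
#' @export
gen_recordings <- function(bundle, map, noise = noise_model(),
                           regions = default_regions(map$n_sites)) {
  stopifnot(inherits(noise, "noise_model"))
  regions <- as.character(regions)
  assert_that(length(regions) == map$n_sites,
              sprintf("regions has length %d but the map has %d sites",
                      length(regions), map$n_sites))
  resp <- apply_ground_truth(map, bundle)
  if (noise$sd > 0) {
    eps <- withr::with_seed(noise$seed,
      matrix(stats::rnorm(length(resp), sd = noise$sd),
             nrow(resp), ncol(resp)))
    resp <- resp + eps
  }
  colnames(resp) <- sprintf("site%03d", seq_len(ncol(resp)))
  recording_set(resp, regions, bundle$stimulus_ids)
}

#' Default V4/IT region layout
#'
#' Splits `n_sites` into a V4 block and an IT block in the 88:168 proportion
#' of the macaque ventral-stream dataset the method targets; at the canonical
#' 256 sites this is exactly 88 V4 and 168 IT sites.
#'
#' @param n_sites total number of sites.
#' @return character vector of region labels.
#' @export
default_regions <- function(n_sites) {
  n_v4 <- round(n_sites * 88 / 256)
  n_v4 <- max(1L, min(n_sites - 1L, n_v4))
  if (n_sites == 1L) return("IT")
  c(rep("V4", n_v4), rep("IT", n_sites - n_v4))
}
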