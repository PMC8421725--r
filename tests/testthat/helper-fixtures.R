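# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; no data files.

tiny_bundle <- function(n = 12, dims = c(a = 3, b = 4), seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
  })
  activation_bundle(mats, sprintf("s%03d", seq_len(n)))
}

tiny_recordings <- function(bundle, n_sites = 5, regions = NULL, seed = 2) {
  n <- length(bundle$stimulus_ids)
  if (is.null(regions))
    regions <- rep(c("V4", "IT"), length.out = n_sites)
  resp <- withr::with_seed(seed, matrix(rnorm(n * n_sites), n, n_sites))
  recording_set(resp, regions, bundle$stimulus_ids)
}

# Straight-line decoder forward pass, written independently of the package's
# vectorized implementation: explicit loops over stimuli and blocks.
forward_oracle <- function(model, bundle) {
  layers <- model$spec$source_layers
  n <- length(bundle$stimulus_ids)
  out <- matrix(0, n, model$spec$n_outputs)
  for (s in seq_len(n)) {
    h1 <- numeric(0)
    for (i in seq_along(layers)) {
      x <- bundle$matrices[[layers[i]]][s, ]
      z <- as.numeric(x %*% model$blocks[[i]]$W) + model$blocks[[i]]$b
      h1 <- c(h1, pmax(z, 0))
    }
    z2 <- as.numeric(h1 %*% model$W2) + model$b2
    h2 <- pmax(z2, 0)
    out[s, ] <- as.numeric(h2 %*% model$Wout) + model$bout
  }
  out
}
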