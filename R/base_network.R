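# A small trainable reference network for the pruning harness: a 3-layer
# ReLU perceptron trained on a seeded synthetic classification task. It plays
# the role of the "base ANN" whose hidden activations feed the decoder, at a
# scale where a full prune -> re-extract -> re-train sweep runs in seconds.

#' Synthetic classification task for the reference base network
#'
#' Draws `n` points from `n_classes` Gaussian clusters with seeded random
#' means (separation ~2 sd), the fixture the reference network is trained on.
#'
#' @param n number of samples.
#' @param d input dimension.
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @return list with `X` (`[n, d]`), integer labels `y` in `1:n_classes`,
#'   and `stimulus_ids`.
#' @export
gen_base_task <- function(n, d, n_classes = 4L, seed) {
  withr::with_seed(as.integer(seed), {
    mu <- matrix(stats::rnorm(n_classes * d, sd = 2), n_classes, d)
    y <- sample.int(n_classes, n, replace = TRUE)
    X <- mu[y, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
  })
  list(X = X, y = y, stimulus_ids = sprintf("s%04d", seq_len(n) - 1L))
}

#' Build the reference base network
#'
#' @param input_dim input dimension.
#' @param hidden_dims integer vector of two hidden widths.
#' @param n_classes output classes.
#' @param seed integer initialization seed.
#' @return an object of class `base_network`.
#' @export
make_base_network <- function(input_dim, hidden_dims = c(32L, 24L),
                              n_classes = 4L, seed = 1L) {
  assert_that(length(hidden_dims) == 2L, "hidden_dims must have length 2")
  dims <- c(input_dim, hidden_dims, n_classes)
  withr::with_seed(as.integer(seed), {
    layers <- lapply(1:3, function(i)
      list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L],
                                   sd = sqrt(2 / dims[i])),
                      dims[i], dims[i + 1L]),
           b = numeric(dims[i + 1L])))
  })
  structure(list(layers = layers, dims = dims), class = "base_network")
}

# Forward pass returning hidden activations and logits.
base_forward <- function(net, X) {
  H1 <- relu(sweep(X %*% net$layers[[1L]]$W, 2, net$layers[[1L]]$b, "+"))
  H2 <- relu(sweep(H1 %*% net$layers[[2L]]$W, 2, net$layers[[2L]]$b, "+"))
  logits <- sweep(H2 %*% net$layers[[3L]]$W, 2, net$layers[[3L]]$b, "+")
  list(H1 = H1, H2 = H2, logits = logits)
}

#' Train the reference base network on its classification fixture
#'
#' Full-batch Adam on the softmax cross-entropy; small and deterministic.
#'
#' @param net a [make_base_network()] object.
#' @param X,y task data from [gen_base_task()].
#' @param epochs training epochs (default 150).
#' @param learning_rate Adam step size (default 1e-2).
#' @return the trained `base_network`, with an `accuracy` field (training
#'   accuracy, for sanity only).
#' @export
train_base_network <- function(net, X, y, epochs = 150L,
                               learning_rate = 1e-2) {
  n <- nrow(X)
  Yhot <- matrix(0, n, net$dims[4L])
  Yhot[cbind(seq_len(n), y)] <- 1
  params <- unlist(lapply(net$layers, function(l) list(l$W, l$b)),
                   recursive = FALSE)
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    fw <- base_forward(net, X)
    Z <- fw$logits - apply(fw$logits, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    dZ3 <- (P - Yhot) / n
    g <- list(crossprod(fw$H2, dZ3), colSums(dZ3))
    dH2 <- dZ3 %*% t(net$layers[[3L]]$W)
    dZ2 <- dH2 * (fw$H2 > 0)
    g <- c(list(crossprod(fw$H1, dZ2), colSums(dZ2)), g)
    dH1 <- dZ2 %*% t(net$layers[[2L]]$W)
    dZ1 <- dH1 * (fw$H1 > 0)
    g <- c(list(crossprod(X, dZ1), colSums(dZ1)), g)
    corr <- learning_rate * sqrt(1 - beta2^t) / (1 - beta1^t)
    for (j in seq_along(params)) {
      m1[[j]] <- beta1 * m1[[j]] + (1 - beta1) * g[[j]]
      m2[[j]] <- beta2 * m2[[j]] + (1 - beta2) * g[[j]]^2
      params[[j]] <- params[[j]] - corr * m1[[j]] / (sqrt(m2[[j]]) + eps)
    }
    for (i in 1:3) {
      net$layers[[i]]$W <- params[[2L * i - 1L]]
      net$layers[[i]]$b <- params[[2L * i]]
    }
  }
  fw <- base_forward(net, X)
  net$accuracy <- mean(max.col(fw$logits) == y)
  net
}

#' Extract hidden-layer activations from the reference base network
#'
#' Produces the activation bundle the decoder consumes, with layers `"h1"`
#' and `"h2"` (post-ReLU hidden activations).
#'
#' @param net a `base_network`.
#' @param X stimulus matrix `[n, input_dim]`.
#' @param stimulus_ids character IDs, one per row.
#' @return an [activation_bundle()].
#' @export
extract_activations <- function(net, X, stimulus_ids) {
  fw <- base_forward(net, X)
  activation_bundle(list(h1 = fw$H1, h2 = fw$H2), stimulus_ids)
}

# Weight matrices of the base network (biases excluded), for pruning.
base_weights <- function(net) lapply(net$layers, `[[`, "W")

set_base_weights <- function(net, Ws) {
  for (i in seq_along(Ws)) net$layers[[i]]$W <- Ws[[i]]
  net
}
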