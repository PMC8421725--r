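#' Activation bundle: per-layer ANN activations for a set of stimuli
#'
#' An activation bundle holds one real matrix per named source layer of an
#' artificial network, with rows indexed by stimulus. All layers must share
#' the same stimuli in the same row order. It is the container fed to the
#' nonlinear decoder and the linear baseline.
#'
#' @param matrices named list of numeric matrices, one per layer, each with
#'   `n_stimuli` rows. Layer order is the list order.
#' @param stimulus_ids character vector of unique stimulus identifiers, one
#'   per row.
#' @return an object of class `activation_bundle` with fields `layer_names`,
#'   `matrices`, and `stimulus_ids`.
#' @examples
#' b <- activation_bundle(
#'   list(conv3 = matrix(rnorm(20), 5), fc = matrix(rnorm(15), 5)),
#'   sprintf("img%02d", 1:5))
#' b$layer_names
#' @export
activation_bundle <- function(matrices, stimulus_ids) {
  assert_that(is.list(matrices) && length(matrices) >= 1L,
              "matrices must be a nonempty named list of matrices")
  nms <- names(matrices)
  assert_that(!is.null(nms) && all(nzchar(nms)) && anyDuplicated(nms) == 0L,
              "layer names must be unique and nonempty")
  stimulus_ids <- as.character(stimulus_ids)
  assert_that(anyDuplicated(stimulus_ids) == 0L,
              "stimulus_ids must be unique")
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (nm in nms) {
    m <- matrices[[nm]]
    assert_that(nrow(m) == length(stimulus_ids),
                sprintf("layer '%s' has %d rows but there are %d stimulus_ids",
                        nm, nrow(m), length(stimulus_ids)))
    assert_that(ncol(m) >= 1L, sprintf("layer '%s' has zero columns", nm))
  }
  structure(list(layer_names = nms, matrices = matrices,
                 stimulus_ids = stimulus_ids),
            class = "activation_bundle")
}

#' @export
print.activation_bundle <- function(x, ...) {
  cat(sprintf("<activation_bundle> %d stimuli, %d layer(s)\n",
              length(x$stimulus_ids), length(x$layer_names)))
  for (nm in x$layer_names)
    cat(sprintf("  %s: %d units\n", nm, ncol(x$matrices[[nm]])))
  invisible(x)
}

#' Recording set: normalized firing rates per site per stimulus
#'
#' Holds a stimuli-by-sites matrix of normalized firing rates (responses
#' referenced to a blank gray stimulus, hence dimensionless) together with a
#' brain-region label per recording site (e.g. `"V4"`, `"IT"`).
#'
#' @param responses numeric matrix, `n_stimuli` rows by `n_sites` columns.
#' @param site_regions character vector of region labels, one per site.
#' @param stimulus_ids character vector of unique stimulus identifiers, one
#'   per row.
#' @return an object of class `recording_set`.
#' @export
recording_set <- function(responses, site_regions, stimulus_ids) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  stimulus_ids <- as.character(stimulus_ids)
  site_regions <- as.character(site_regions)
  assert_that(nrow(responses) == length(stimulus_ids),
              "responses must have one row per stimulus_id")
  assert_that(ncol(responses) == length(site_regions),
              "site_regions must have one label per response column")
  assert_that(all(nzchar(site_regions)),
              "every site needs a nonempty region label")
  assert_that(anyDuplicated(stimulus_ids) == 0L,
              "stimulus_ids must be unique")
  structure(list(responses = responses, site_regions = site_regions,
                 stimulus_ids = stimulus_ids),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  tab <- table(x$site_regions)
  cat(sprintf("<recording_set> %d stimuli x %d sites (%s)\n",
              nrow(x$responses), ncol(x$responses),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Restrict activations and recordings to their shared stimuli
#'
#' Both containers are restricted to the intersection of their stimulus IDs
#' and reordered so rows match one-to-one. The output row order follows the
#' activation bundle's order restricted to the intersection; the operation is
#' idempotent.
#'
#' @param bundle an [activation_bundle()].
#' @param recordings a [recording_set()].
#' @return a list with elements `bundle` and `recordings`, row-aligned.
#' @export
align_by_stimulus <- function(bundle, recordings) {
  stopifnot(inherits(bundle, "activation_bundle"),
            inherits(recordings, "recording_set"))
  keep <- bundle$stimulus_ids[bundle$stimulus_ids %in% recordings$stimulus_ids]
  if (length(keep) == 0L)
    stop(sprintf(paste0("no shared stimuli: bundle has %d IDs, recordings ",
                        "have %d IDs, intersection is empty"),
                 length(bundle$stimulus_ids), length(recordings$stimulus_ids)),
         call. = FALSE)
  bi <- match(keep, bundle$stimulus_ids)
  ri <- match(keep, recordings$stimulus_ids)
  b <- activation_bundle(
    lapply(bundle$matrices, function(m) m[bi, , drop = FALSE]), keep)
  r <- recording_set(recordings$responses[ri, , drop = FALSE],
                     recordings$site_regions, keep)
  list(bundle = b, recordings = r)
}

#' Deterministic train/validation row split
#'
#' Rows are permuted with a seeded RNG; the first `floor(fraction * n_rows)`
#' go to training, the remainder to validation. Used to hold out stimuli for
#' decoder validation and early stopping.
#'
#' @param n_rows total number of rows (stimuli), at least 2.
#' @param fraction training fraction, strictly between 0 and 1. Default 0.8.
#' @param seed integer seed; the split is fully determined by it.
#' @return an object of class `split_index` with integer fields `train_rows`
#'   and `val_rows` (disjoint, jointly covering `1:n_rows`), plus the `seed`
#'   and `fraction` used.
#' @export
split_rows <- function(n_rows, fraction = 0.8, seed) {
  assert_that(is_count(n_rows) && n_rows >= 2, "n_rows must be an integer >= 2")
  assert_that(is.numeric(fraction) && length(fraction) == 1L &&
                fraction > 0 && fraction < 1,
              "fraction must lie strictly between 0 and 1")
  n_train <- floor(fraction * n_rows)
  if (n_train < 1L || n_train >= n_rows)
    stop("fraction yields an empty train or validation set", call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample.int(n_rows))
  structure(list(train_rows = sort(perm[seq_len(n_train)]),
                 val_rows = sort(perm[(n_train + 1L):n_rows]),
                 seed = as.integer(seed), fraction = fraction),
            class = "split_index")
}

#' Spatially pool convolutional feature maps per channel
#'
#' Convolutional activations arrive as a 4-D array (stimuli x height x width
#' x channels). Before entering the decoder they are reduced to one value per
#' channel by averaging over the spatial grid. Rank-2 input (already
#' vectorized) passes through unchanged.
#'
#' @param x numeric 4-D array `[n, H, W, C]`, or a matrix.
#' @return numeric matrix `[n, C]` of per-channel spatial means.
#' @export
pool_spatial <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  assert_that(length(d) == 4L,
              "pool_spatial expects a matrix or a 4-D array [n, H, W, C]")
  out <- apply(x, c(1L, 4L), mean)
  dim(out) <- c(d[1L], d[4L])
  out
}

#' Seeded Gaussian random projection for wide activation matrices
#'
#' When a layer's activation dimension `d` exceeds `k`, the matrix is
#' projected to `k` dimensions with a seeded random matrix whose entries are
#' i.i.d. Gaussian scaled by `1/sqrt(k)`; squared pairwise distances are
#' approximately preserved (Johnson-Lindenstrauss). When `k >= d` the input
#' passes through unchanged. The returned descriptor re-applies the same
#' projection to new rows (e.g. validation stimuli).
#'
#' @param x numeric matrix `[n, d]`.
#' @param k target dimension (default 1024).
#' @param seed integer seed for the projection matrix.
#' @return list with `matrix` (the projected data) and `projection`, a
#'   descriptor usable with [apply_projection()].
#' @export
reduce_dims <- function(x, k = 1024L, seed) {
  x <- as.matrix(x)
  assert_that(is_count(k), "k must be a positive integer")
  d <- ncol(x)
  if (k >= d) {
    proj <- structure(list(kind = "identity", d = d), class = "dim_projection")
    return(list(matrix = x, projection = proj))
  }
  P <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(d * k), d, k) / sqrt(k))
  proj <- structure(list(kind = "gaussian", d = d, k = as.integer(k),
                         seed = as.integer(seed), P = P),
                    class = "dim_projection")
  list(matrix = x %*% P, projection = proj)
}

#' Apply a fitted dimension-reduction descriptor to new rows
#'
#' @param projection a descriptor returned by [reduce_dims()].
#' @param x numeric matrix with the same column count the descriptor was
#'   created for.
#' @return the projected matrix.
#' @export
apply_projection <- function(projection, x) {
  stopifnot(inherits(projection, "dim_projection"))
  x <- as.matrix(x)
  assert_that(ncol(x) == projection$d,
              sprintf("expected %d columns, got %d", projection$d, ncol(x)))
  if (projection$kind == "identity") x else x %*% projection$P
}
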