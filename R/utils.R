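# Internal helpers shared across modules.

# Deterministic derived seeds: mix a base seed with a small offset while
# staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483647
  as.integer(s)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 1
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Column-bind the matrices of the named layers, in the given order.
concat_layers <- function(bundle, layers = bundle$layer_names) {
  missing <- setdiff(layers, bundle$layer_names)
  assert_that(length(missing) == 0L,
              paste0("bundle is missing source layer(s): ",
                     paste(missing, collapse = ", ")))
  do.call(cbind, lapply(layers, function(nm) bundle$matrices[[nm]]))
}
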