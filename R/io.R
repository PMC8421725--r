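#' Write / read an activation bundle
#'
#' A bundle is stored as a directory: `manifest.json` records the layer order
#' and stimulus IDs, and each layer's matrix is a tab-separated table
#' `<layer>.tsv` (one row per stimulus, no header beyond column names).
#' Round-trips are exact for IDs and layer order and value-level (15
#' significant digits) for activations.
#'
#' @param bundle an [activation_bundle()].
#' @param path directory to create or overwrite.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` returns the
#'   reconstructed [activation_bundle()].
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "activation_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "nrp-activation-bundle-v1",
                   layer_names = bundle$layer_names,
                   stimulus_ids = bundle$stimulus_ids)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in bundle$layer_names) {
    data.table::fwrite(data.table::as.data.table(bundle$matrices[[nm]]),
                       file.path(path, paste0(nm, ".tsv")), sep = "\t")
  }
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  assert_that(file.exists(mf),
              sprintf("no bundle manifest at '%s'", mf))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  assert_that(identical(manifest$format, "nrp-activation-bundle-v1"),
              "unrecognized bundle format")
  ids <- as.character(manifest$stimulus_ids)
  if (anyDuplicated(ids))
    stop("bundle file invalid: duplicate stimulus_ids", call. = FALSE)
  mats <- lapply(manifest$layer_names, function(nm) {
    f <- file.path(path, paste0(nm, ".tsv"))
    assert_that(file.exists(f), sprintf("missing layer file '%s'", f))
    as.matrix(data.table::fread(f))
  })
  names(mats) <- manifest$layer_names
  activation_bundle(mats, ids)
}

#' Write / read a recording set
#'
#' Recordings are a single human-inspectable tab-separated table: the first
#' column is `stimulus_id`, and each site column's header is
#' `<site name>:<region label>`, so the region assignment travels in the
#' header row.
#'
#' @param recordings a [recording_set()].
#' @param path file to write.
#' @return `write_recordings` returns `path` invisibly; `read_recordings`
#'   returns the reconstructed [recording_set()].
#' @export
write_recordings <- function(recordings, path) {
  stopifnot(inherits(recordings, "recording_set"))
  n_sites <- ncol(recordings$responses)
  site_names <- colnames(recordings$responses)
  if (is.null(site_names))
    site_names <- sprintf("site%03d", seq_len(n_sites))
  dt <- data.table::data.table(stimulus_id = recordings$stimulus_ids)
  resp <- data.table::as.data.table(recordings$responses)
  data.table::setnames(resp, paste0(site_names, ":", recordings$site_regions))
  data.table::fwrite(cbind(dt, resp), path, sep = "\t")
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  assert_that(file.exists(path), sprintf("no recordings file at '%s'", path))
  dt <- data.table::fread(path, sep = "\t", check.names = FALSE)
  assert_that(identical(names(dt)[1L], "stimulus_id"),
              "recordings file invalid: first column must be stimulus_id")
  ids <- as.character(dt[["stimulus_id"]])
  if (anyDuplicated(ids))
    stop("recordings file invalid: duplicate stimulus_id values",
         call. = FALSE)
  site_cols <- names(dt)[-1L]
  has_region <- grepl(":", site_cols, fixed = TRUE)
  if (!all(has_region))
    stop(sprintf(paste0("recordings file invalid: site column(s) missing a ",
                        "region label (expected 'site:region'): %s"),
                 paste(site_cols[!has_region], collapse = ", ")),
         call. = FALSE)
  site_names <- sub(":[^:]*$", "", site_cols)
  regions <- sub("^.*:", "", site_cols)
  resp <- as.matrix(dt[, -1L, with = FALSE])
  colnames(resp) <- site_names
  recording_set(resp, regions, ids)
}

#' Serialize / restore a decoder model
#'
#' The full model — architecture spec and every weight array — is stored as
#' one JSON archive so trained decoders can be reloaded for evaluation.
#' Weights round-trip at full double precision.
#'
#' @param model an `nrp_model` from [build_nrp()] or [train_nrp()].
#' @param path file to write.
#' @return `write_nrp_model` returns `path` invisibly; `read_nrp_model`
#'   returns the model.
#' @export
write_nrp_model <- function(model, path) {
  stopifnot(inherits(model, "nrp_model"))
  pack <- function(W) list(data = as.numeric(W), dims = dim(W))
  blocks <- lapply(model$blocks, function(b)
    list(W = pack(b$W), b = as.numeric(b$b)))
  names(blocks) <- model$spec$source_layers
  enc <- list(
    format = "nrp-model-v1",
    spec = unclass(model$spec),
    blocks = blocks,
    W2 = pack(model$W2), b2 = as.numeric(model$b2),
    Wout = pack(model$Wout), bout = as.numeric(model$bout))
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nrp_model
#' @export
read_nrp_model <- function(path) {
  assert_that(file.exists(path), sprintf("no model archive at '%s'", path))
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(enc$format, "nrp-model-v1"),
              "unrecognized model archive format")
  spec <- do.call(nrp_spec, enc$spec)
  unpack <- function(p) matrix(as.numeric(p$data), p$dims[1L], p$dims[2L])
  blocks <- lapply(spec$source_layers, function(nm)
    list(W = unpack(enc$blocks[[nm]]$W),
         b = as.numeric(enc$blocks[[nm]]$b)))
  names(blocks) <- spec$source_layers
  structure(list(spec = spec, blocks = blocks,
                 W2 = unpack(enc$W2), b2 = as.numeric(enc$b2),
                 Wout = unpack(enc$Wout), bout = as.numeric(enc$bout)),
            class = "nrp_model")
}
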