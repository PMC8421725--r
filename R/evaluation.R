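#' Mean absolute error between predicted and measured responses
#'
#' The distance metric behind the NRP-error: the mean over all entries of
#' `|pred - meas|`. Lower values mean the decoder predicts the recordings
#' more faithfully.
#'
#' @param pred,meas numeric matrices of identical nonempty shape.
#' @return scalar mean absolute error.
#' @export
mae <- function(pred, meas) {
  pred <- as.matrix(pred); meas <- as.matrix(meas)
  assert_that(all(dim(pred) == dim(meas)),
              sprintf("shape mismatch: pred is %dx%d, meas is %dx%d",
                      nrow(pred), ncol(pred), nrow(meas), ncol(meas)))
  assert_that(length(pred) > 0L, "mae of empty matrices is undefined")
  if (anyNA(pred) || anyNA(meas) || any(!is.finite(pred)) ||
      any(!is.finite(meas)))
    stop("mae: non-finite entries in input", call. = FALSE)
  mean(abs(pred - meas))
}

#' Per-region NRP-error report
#'
#' Computes the mean absolute error separately for each brain region (over
#' that region's site columns and the requested stimulus rows) and averages
#' the region errors — unweighted by site count — into the overall NRP-error.
#' Regions are reported in lexicographic order for determinism.
#'
#' @param pred numeric matrix of predicted responses, one column per site.
#' @param recordings a [recording_set()] with matching site count and rows.
#' @param rows integer vector of stimulus rows to score (default: all).
#' @param model_descriptor optional string identifying the model scored.
#' @return an object of class `nrp_report` with fields `per_region_error`
#'   (named numeric), `overall_error`, `n_stimuli_eval`, `model_descriptor`.
#' @export
nrp_error_by_region <- function(pred, recordings,
                                rows = seq_len(nrow(pred)),
                                model_descriptor = "") {
  stopifnot(inherits(recordings, "recording_set"))
  pred <- as.matrix(pred)
  assert_that(ncol(pred) == ncol(recordings$responses),
              "pred column count must equal the recording site count")
  assert_that(nrow(pred) == nrow(recordings$responses),
              "pred row count must equal the recording row count")
  rows <- as.integer(rows)
  assert_that(length(rows) > 0L, "rows must be nonempty")
  regions <- sort(unique(recordings$site_regions))
  errs <- numeric(0)
  for (rg in regions) {
    cols <- which(recordings$site_regions == rg)
    if (length(cols) == 0L) {
      warning(sprintf("region '%s' has no sites; excluded", rg))
      next
    }
    errs[rg] <- mae(pred[rows, cols, drop = FALSE],
                    recordings$responses[rows, cols, drop = FALSE])
  }
  structure(list(per_region_error = errs,
                 overall_error = mean(errs),
                 n_stimuli_eval = length(rows),
                 model_descriptor = model_descriptor),
            class = "nrp_report")
}

#' @export
print.nrp_report <- function(x, ...) {
  cat("<nrp_report>", x$model_descriptor, "\n")
  for (rg in names(x$per_region_error))
    cat(sprintf("  %-4s NRP-error: %.4f\n", rg, x$per_region_error[[rg]]))
  cat(sprintf("  overall (unweighted region mean): %.4f over %d stimuli\n",
              x$overall_error, x$n_stimuli_eval))
  invisible(x)
}
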