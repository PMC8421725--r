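#' Fit the linear-regression baseline
#'
#' The comparator for the nonlinear decoder: an affine map from the
#' concatenated source-layer activations to all recording sites, fit on the
#' training rows by closed-form normal equations. An optional ridge penalty
#' `lambda` is added to the Gram diagonal (the intercept is never penalized;
#' it is handled by centering). At `lambda = 0` this is plain multi-output
#' least squares, which requires the training Gram matrix to be nonsingular
#' (`n_train > d` in general position).
#'
#' @param bundle an [activation_bundle()], row-aligned with `recordings`.
#' @param recordings a [recording_set()].
#' @param split a [split_rows()] index; only `train_rows` are used for
#'   fitting.
#' @param ridge_lambda nonnegative ridge penalty. `NULL` (default) uses
#'   `1e-3 * trace(Gram) / d`, a scale-aware mild penalty that keeps wide
#'   activation matrices well-posed; use `0` for plain least squares.
#' @return an object of class `linear_map_model` with fields `coefficients`
#'   (`[sum(d_layers), n_sites]`), `intercepts`, `ridge_lambda`,
#'   `source_layers`.
#' @export
fit_linear <- function(bundle, recordings, split, ridge_lambda = NULL) {
  stopifnot(inherits(bundle, "activation_bundle"),
            inherits(recordings, "recording_set"),
            inherits(split, "split_index"))
  assert_that(identical(bundle$stimulus_ids, recordings$stimulus_ids),
              "bundle and recordings must be aligned (same stimuli, same order)")
  X <- concat_layers(bundle)
  tr <- split$train_rows
  Xtr <- X[tr, , drop = FALSE]
  Ytr <- recordings$responses[tr, , drop = FALSE]
  d <- ncol(Xtr)
  xm <- colMeans(Xtr)
  ym <- colMeans(Ytr)
  Xc <- sweep(Xtr, 2, xm)
  Yc <- sweep(Ytr, 2, ym)
  G <- crossprod(Xc)
  if (is.null(ridge_lambda))
    ridge_lambda <- 1e-3 * sum(diag(G)) / d
  assert_that(ridge_lambda >= 0, "ridge_lambda must be nonnegative")
  A <- G + diag(ridge_lambda, d)
  beta <- tryCatch(
    solve(A, crossprod(Xc, Yc)),
    error = function(e) {
      if (ridge_lambda == 0)
        stop(paste0("linear fit is underdetermined (singular Gram matrix, ",
                    "likely d >= n_train); set ridge_lambda > 0"),
             call. = FALSE)
      stop(e)
    })
  intercepts <- as.numeric(ym - crossprod(beta, xm))
  structure(list(coefficients = beta, intercepts = intercepts,
                 ridge_lambda = ridge_lambda,
                 source_layers = bundle$layer_names),
            class = "linear_map_model")
}

#' Predict responses with the linear baseline
#'
#' @param model a [fit_linear()] model.
#' @param bundle an [activation_bundle()] with matching concatenated
#'   dimension.
#' @return numeric matrix `[n_stimuli, n_sites]`.
#' @export
predict_linear <- function(model, bundle) {
  stopifnot(inherits(model, "linear_map_model"),
            inherits(bundle, "activation_bundle"))
  X <- concat_layers(bundle)
  assert_that(ncol(X) == nrow(model$coefficients),
              sprintf("bundle has %d concatenated dims, model expects %d",
                      ncol(X), nrow(model$coefficients)))
  sweep(X %*% model$coefficients, 2, model$intercepts, "+")
}

#' Coefficient of determination of the linear baseline, per site
#'
#' For each site `s`, `R^2 = 1 - SS_res / SS_tot`, with the total sum of
#' squares taken about the site's mean response over the scored rows. A low
#' mean R-squared is the diagnostic that the activation-to-response
#' relationship is not linear. Sites with zero response variance over the
#' scored rows have undefined R-squared; they are excluded from the mean with
#' a warning.
#'
#' @param model a [fit_linear()] model.
#' @param bundle an [activation_bundle()], row-aligned with `recordings`.
#' @param recordings a [recording_set()].
#' @param rows integer rows to score (e.g. a validation split); nonempty.
#' @return list with `per_site` (numeric, `NA` for zero-variance sites) and
#'   `mean` (over defined sites).
#' @export
r_squared <- function(model, bundle, recordings,
                      rows = seq_along(recordings$stimulus_ids)) {
  rows <- as.integer(rows)
  assert_that(length(rows) > 0L, "rows must be nonempty")
  pred <- predict_linear(model, bundle)[rows, , drop = FALSE]
  y <- recordings$responses[rows, , drop = FALSE]
  ss_res <- colSums((y - pred)^2)
  ss_tot <- colSums(sweep(y, 2, colMeans(y))^2)
  r2 <- 1 - ss_res / ss_tot
  degenerate <- ss_tot == 0
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance site(s) excluded from mean R-squared",
                    sum(degenerate)))
    r2[degenerate] <- NA_real_
  }
  list(per_site = r2, mean = mean(r2, na.rm = TRUE))
}
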