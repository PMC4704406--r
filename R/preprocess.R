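#' Spectral window definition for plasma calibration
#'
#' The instrument records 5012-926 cm^-1, but only three regions carry
#' calibration-grade signal for aqueous plasma: 2971.7-2432.4,
#' 2272.4-1716.8 and 1543.2-964.5 cm^-1. The two regions 3626.5-2970.7 and
#' 1716.8-1543.2 cm^-1 are dominated by water absorption and are excluded;
#' 5012.0-3626.5 cm^-1 carries little analyte information. Intensity effects
#' are suppressed by dividing each retained transmittance by the mean
#' transmittance of a reference band at 1492-1481 cm^-1.
#'
#' All intervals are closed on both ends; a grid point on a shared boundary
#' (e.g. 1716.8 cm^-1) belongs to the retained window.
#'
#' @param retained List of numeric length-2 vectors `c(low, high)` (cm^-1).
#' @param reference_band Numeric `c(low, high)` for the normalisation band;
#'   must lie inside a retained window.
#' @param reference_stat `"mean"` (default) or `"median"`: statistic used to
#'   summarise the reference band.
#' @return A `spectral_windows` object.
#' @export
spectral_windows <- function(retained = list(c(2432.4, 2971.7),
                                             c(1716.8, 2272.4),
                                             c(964.5, 1543.2)),
                             reference_band = c(1481, 1492),
                             reference_stat = c("mean", "median")) {
  reference_stat <- match.arg(reference_stat)
  retained <- lapply(retained, function(iv) sort(as.numeric(iv)))
  ivs <- do.call(rbind, retained)
  o <- order(ivs[, 1])
  ivs <- ivs[o, , drop = FALSE]
  if (nrow(ivs) > 1 && any(ivs[-1, 1] <= ivs[-nrow(ivs), 2])) {
    stop("retained intervals must be pairwise disjoint", call. = FALSE)
  }
  reference_band <- sort(as.numeric(reference_band))
  inside <- any(ivs[, 1] <= reference_band[1] & reference_band[2] <= ivs[, 2])
  if (!inside) {
    stop("reference band must lie inside a retained interval", call. = FALSE)
  }
  structure(list(retained = retained,
                 excluded_water = list(c(2970.7, 3626.5), c(1543.2, 1716.8)),
                 excluded_low_info = list(c(3626.5, 5012.0)),
                 reference_band = reference_band,
                 reference_stat = reference_stat),
            class = "spectral_windows")
}

#' @export
print.spectral_windows <- function(x, ...) {
  ivs <- vapply(x$retained, function(iv) sprintf("%.1f-%.1f", iv[2], iv[1]),
                character(1))
  cat("<spectral_windows> retained:", paste(ivs, collapse = ", "),
      sprintf("cm^-1; reference band %.0f-%.0f cm^-1 (%s)\n",
              x$reference_band[2], x$reference_band[1], x$reference_stat))
  invisible(x)
}

.in_windows <- function(wn, intervals) {
  keep <- rep(FALSE, length(wn))
  for (iv in intervals) keep <- keep | (wn >= iv[1] & wn <= iv[2])
  keep
}

#' Restrict spectra to the retained wavenumber windows
#'
#' Pure filter: keeps exactly the grid points lying inside any retained
#' closed interval, preserving order. Applying it twice equals applying it
#' once.
#'
#' @param x A `spectra_set`.
#' @param windows A [spectral_windows()] definition.
#' @return A `spectra_set` on the reduced grid.
#' @export
select_windows <- function(x, windows = spectral_windows()) {
  stopifnot(inherits(x, "spectra_set"), inherits(windows, "spectral_windows"))
  keep <- .in_windows(x$wavenumbers, windows$retained)
  if (!any(keep)) {
    stop("no grid point falls inside any retained window; ",
         "grid/window mismatch", call. = FALSE)
  }
  spectra_set(x$sample_id, x$replicate, x$wavenumbers[keep],
              x$transmittance[, keep, drop = FALSE])
}

#' Normalise transmittance to the reference band
#'
#' Divides every transmittance value of a spectrum by that spectrum's
#' reference-band statistic (mean %T over grid points in 1492-1481 cm^-1 by
#' default), yielding dimensionless corrected transmittance ratios that are
#' invariant under global intensity rescaling.
#'
#' The reference statistic is always computed on the grid passed in, so
#' normalise either before or after [select_windows()] (the reference band
#' lies inside a retained window, making the two orders equivalent).
#'
#' @inheritParams select_windows
#' @return A list with `sample_id`, `replicate`, `wavenumbers` and `ratios`
#'   (matrix of corrected transmittance), class `transmittance_ratios`.
#' @export
reference_normalize <- function(x, windows = spectral_windows()) {
  stopifnot(inherits(x, "spectra_set"), inherits(windows, "spectral_windows"))
  band <- windows$reference_band
  in_band <- x$wavenumbers >= band[1] & x$wavenumbers <= band[2]
  if (!any(in_band)) {
    stop(sprintf("no grid point in the reference band %.0f-%.0f cm^-1",
                 band[2], band[1]), call. = FALSE)
  }
  stat_fun <- if (windows$reference_stat == "median") stats::median else mean
  ref <- apply(x$transmittance[, in_band, drop = FALSE], 1, stat_fun)
  if (any(ref <= 0)) {
    stop("nonpositive reference-band statistic", call. = FALSE)
  }
  ratios <- x$transmittance / ref
  structure(list(sample_id = x$sample_id, replicate = x$replicate,
                 wavenumbers = x$wavenumbers, ratios = ratios),
            class = "transmittance_ratios")
}

#' Convert corrected transmittance ratios to absorbance
#'
#' Elementwise `A = -log10(ratio)`. Ratios must be strictly positive.
#'
#' @param x A `transmittance_ratios` object (or a positive numeric
#'   matrix/vector).
#' @return For a `transmittance_ratios` input, an `absorbance_features`
#'   object (row ids, wavenumbers, absorbance matrix); otherwise a numeric
#'   object of the same shape.
#' @export
to_absorbance <- function(x) {
  if (inherits(x, "transmittance_ratios")) {
    if (any(x$ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
    structure(list(sample_id = x$sample_id, replicate = x$replicate,
                   wavenumbers = x$wavenumbers,
                   absorbance = -log10(x$ratios)),
              class = "absorbance_features")
  } else {
    if (any(x <= 0)) stop("ratios must be > 0", call. = FALSE)
    -log10(x)
  }
}

#' Full spectral preprocessing chain
#'
#' [select_windows()] then [reference_normalize()] then [to_absorbance()]:
#' raw %T spectra to the absorbance feature matrix used for calibration.
#'
#' @inheritParams select_windows
#' @return An `absorbance_features` object.
#' @export
#' @examples
#' ds <- synthetic_study(n = 6, specs = analyte_registry("glucose"), seed = 7)
#' feats <- preprocess_spectra(ds$spectra)
#' dim(feats$absorbance)
preprocess_spectra <- function(x, windows = spectral_windows()) {
  to_absorbance(reference_normalize(select_windows(x, windows), windows))
}

#' @export
print.absorbance_features <- function(x, ...) {
  cat(sprintf("<absorbance_features> %d spectra x %d retained wavenumbers\n",
              nrow(x$absorbance), length(x$wavenumbers)))
  invisible(x)
}

#' Centre and scale predictors and response
#'
#' Autoscales every absorbance column and the response to mean 0, SD 1 (n-1
#' denominator), recording the transform so it can be applied identically to
#' new rows and inverted on predictions. Zero-variance predictor columns are
#' dropped with a warning; a zero-variance response is an error.
#'
#' @param X Numeric predictor matrix (or `absorbance_features`).
#' @param y Numeric response vector.
#' @return List with `X` (scaled matrix), `y` (scaled vector) and `record`
#'   (a `scaling_record`: centres, scales, kept columns).
#' @export
autoscale <- function(X, y) {
  if (inherits(X, "absorbance_features")) X <- X$absorbance
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to autoscale", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) {
    stop("zero-variance response cannot be autoscaled", call. = FALSE)
  }
  n <- nrow(X)
  x_center <- colMeans(X)
  x_scale <- sqrt(pmax(colSums(X^2) - n * x_center^2, 0) / (n - 1))
  keep <- x_scale > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance predictor column(s) dropped")
  }
  record <- structure(list(x_center = x_center[keep], x_scale = x_scale[keep],
                           keep = which(keep), n_input_cols = ncol(X),
                           y_center = y_center, y_scale = y_scale),
                      class = "scaling_record")
  list(X = scale_features(record, X), y = (y - y_center) / y_scale,
       record = record)
}

#' Apply / invert a stored scaling record
#'
#' `scale_features()` applies the stored column transform (including the
#' zero-variance column drop) to new rows; `unscale_response()` maps scaled
#' predictions back to original response units.
#'
#' @param record A `scaling_record` from [autoscale()].
#' @param X New predictor rows (same columns as the training matrix).
#' @return Scaled matrix.
#' @export
scale_features <- function(record, X) {
  if (inherits(X, "absorbance_features")) X <- X$absorbance
  X <- as.matrix(X)
  if (ncol(X) != record$n_input_cols) {
    stop("column mismatch: expected ", record$n_input_cols, " columns, got ",
         ncol(X), call. = FALSE)
  }
  X <- X[, record$keep, drop = FALSE]
  sweep(sweep(X, 2, record$x_center, "-"), 2, record$x_scale, "/")
}

#' @rdname scale_features
#' @param y_scaled Predictions on the scaled response scale.
#' @export
unscale_response <- function(record, y_scaled) {
  y_scaled * record$y_scale + record$y_center
}
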