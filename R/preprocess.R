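# Spectral preprocessing chain: weighted least-squares baseline (WLSB),
# standard normal variate (SNV), Savitzky-Golay first derivative, mean
# centering, and region selection. The first three act per spectrum; mean
# centering is fitted on calibration rows only.

#' Weighted least-squares baseline correction
#'
#' Iteratively fits a polynomial baseline by weighted least squares,
#' down-weighting points above the current baseline (weight =
#' `asymmetry_weight` for positive residuals, 1 otherwise) so the fit tracks
#' the spectrum's underside. Stops when weights stabilize or after
#' `max_iter` iterations (non-convergence returns the last iterate with a
#' warning, never an error). Returns the spectrum minus the fitted baseline.
#'
#' @param y numeric absorbance vector (or `ir_spectrum`).
#' @param axis wavenumber axis (ignored when `y` is an `ir_spectrum`).
#' @param poly_order polynomial degree (>= 0), default 2.
#' @param asymmetry_weight weight for points above the baseline, in (0, 1).
#' @param max_iter maximum reweighting iterations.
#' @param tol convergence tolerance on the maximum weight change.
#' @return baseline-corrected vector (or `ir_spectrum`), with the fitted
#'   baseline in the `"baseline"` attribute (vector input only).
#' @export
wlsb <- function(y, axis = NULL, poly_order = 2, asymmetry_weight = 0.001,
                 max_iter = 100, tol = 1e-8) {
  if (inherits(y, "ir_spectrum")) {
    corrected <- wlsb(y$absorbance, as.numeric(y$axis), poly_order,
                      asymmetry_weight, max_iter, tol)
    return(new_spectrum(y$axis, as.numeric(corrected), y$meta))
  }
  if (poly_order < 0) stop("`poly_order` must be >= 0", call. = FALSE)
  if (asymmetry_weight <= 0 || asymmetry_weight >= 1) {
    stop("`asymmetry_weight` must be in (0, 1)", call. = FALSE)
  }
  n <- length(y)
  x <- if (is.null(axis)) seq_len(n) else as.numeric(axis)
  # scaled power basis is numerically adequate for the low orders used here
  xs <- (x - mean(x)) / (max(x) - min(x))
  B <- outer(xs, 0:poly_order, `^`)
  w <- rep(1, n)
  baseline <- rep(0, n)
  converged <- FALSE
  scale_y <- max(abs(y), 1)
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(B, y, w)
    baseline_new <- drop(B %*% fit$coefficients)
    stable_baseline <- max(abs(baseline_new - baseline)) < 1e-12 * scale_y && it > 1
    baseline <- baseline_new
    w_new <- ifelse(y - baseline > 0, asymmetry_weight, 1)
    if (max(abs(w_new - w)) < tol || stable_baseline) { converged <- TRUE; break }
    w <- w_new
  }
  if (!converged && max_iter > 1) {
    warning("WLSB did not converge; returning last iterate", call. = FALSE)
  }
  structure(y - baseline, baseline = baseline)
}

#' Standard normal variate normalization
#'
#' Per-spectrum centering and scaling to unit standard deviation; removes
#' additive offsets and multiplicative gain.
#'
#' @param y numeric vector (or `ir_spectrum`) with nonzero standard deviation.
#' @return normalized vector (or `ir_spectrum`).
#' @export
snv <- function(y) {
  if (inherits(y, "ir_spectrum")) {
    return(new_spectrum(y$axis, snv(y$absorbance), y$meta))
  }
  s <- stats::sd(y)
  if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(mean(y)))) {
    stop("SNV undefined for a (near-)constant spectrum", call. = FALSE)
  }
  (y - mean(y)) / s
}

#' Savitzky-Golay first derivative
#'
#' Polynomial-smoothed first derivative with respect to wavenumber (the
#' index-wise derivative divided by the axis spacing, so results are
#' spacing-invariant). Endpoints are handled by the local polynomial fit
#' within the window.
#'
#' @param y numeric vector (or `ir_spectrum`).
#' @param axis wavenumber axis (needed for the spacing when `y` is a vector).
#' @param window odd filter length, `window >= polyorder + 2`.
#' @param polyorder polynomial order, default 2.
#' @return derivative in AU per cm-1.
#' @export
sg_first_derivative <- function(y, axis = NULL, window = 7, polyorder = 2) {
  if (inherits(y, "ir_spectrum")) {
    return(new_spectrum(y$axis,
                        sg_first_derivative(y$absorbance, y$axis, window, polyorder),
                        y$meta))
  }
  if (window %% 2 != 1 || window < polyorder + 2) {
    stop("`window` must be odd and >= polyorder + 2", call. = FALSE)
  }
  if (window > length(y)) stop("window longer than spectrum", call. = FALSE)
  step <- if (is.null(axis)) 1 else axis_step(as_wn_axis(axis))
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = window, m = 1)) / step
}

#' Fit / apply mean centering
#'
#' `fit_center()` learns column means on calibration rows only;
#' `apply_center()` subtracts those stored means from any matrix (test rows
#' never contribute to the means).
#'
#' @param X numeric matrix (rows = samples).
#' @return `fit_center`: object of class `centerer`; `apply_center`: matrix.
#' @export
fit_center <- function(X) {
  structure(list(means = colMeans(X)), class = "centerer")
}

#' @rdname fit_center
#' @param centerer a fitted `centerer`.
#' @export
apply_center <- function(centerer, X) {
  if (!inherits(centerer, "centerer")) stop("unfitted centerer", call. = FALSE)
  sweep(X, 2, centerer$means, `-`)
}

#' Select a contiguous wavenumber region
#'
#' Keeps columns with `lo <= wavenumber <= hi` (inclusive); bounds that fall
#' between grid points snap outward to the nearest grid point so the stated
#' range is always covered.
#'
#' @param X spectra matrix (columns = wavenumbers) or numeric vector.
#' @param axis the wavenumber axis of the columns.
#' @param lo,hi region bounds in cm-1, `lo < hi`, both inside the axis range.
#' @return the submatrix, with the selected axis in attribute `"axis"`.
#' @export
select_region <- function(X, axis, lo, hi) {
  v <- as.numeric(axis)
  if (lo >= hi) stop("`lo` must be less than `hi`", call. = FALSE)
  if (hi < min(v) || lo > max(v) || lo < min(v) - 1e-9 || hi > max(v) + 1e-9) {
    stop("region bounds outside the axis range", call. = FALSE)
  }
  lo_s <- if (any(v <= lo + 1e-9)) max(v[v <= lo + 1e-9]) else min(v)
  hi_s <- if (any(v >= hi - 1e-9)) min(v[v >= hi - 1e-9]) else max(v)
  sel <- v >= lo_s - 1e-9 & v <= hi_s + 1e-9
  out <- if (is.matrix(X)) X[, sel, drop = FALSE] else X[sel]
  attr(out, "axis") <- v[sel]
  out
}

#' Per-spectrum preprocessing chain
#'
#' Applies, in fixed order, WLSB baseline correction, SNV normalization and
#' the Savitzky-Golay first derivative to every row of a spectra matrix.
#' These steps are sample-wise, so they are independent of any
#' calibration/test split; mean centering (the only fitted step) is handled
#' inside the PLS fit and refitted within every cross-validation fold.
#'
#' @param X spectra matrix (rows = samples).
#' @param axis wavenumber axis of the columns.
#' @param wlsb_order,wlsb_asym,wlsb_max_iter WLSB parameters.
#' @param sg_window,sg_polyorder derivative parameters.
#' @return preprocessed matrix with the axis in attribute `"axis"`.
#' @export
preprocess_spectra <- function(X, axis, wlsb_order = 2, wlsb_asym = 0.001,
                               wlsb_max_iter = 100, sg_window = 7,
                               sg_polyorder = 2) {
  axis_v <- as.numeric(axis)
  out <- t(apply(X, 1, function(row) {
    row <- as.numeric(wlsb(row, axis_v, poly_order = wlsb_order,
                           asymmetry_weight = wlsb_asym,
                           max_iter = wlsb_max_iter))
    row <- snv(row)
    sg_first_derivative(row, axis, window = sg_window, polyorder = sg_polyorder)
  }))
  attr(out, "axis") <- axis_v
  out
}

#' Standard analysis regions
#'
#' Fingerprint windows used by the packaged workflows: 1000-1680 cm-1 for
#' creatinine regression, 1380-1680 cm-1 for albumin regression, and
#' 950-1770 cm-1 for albuminuria classification.
#'
#' @return named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
analysis_regions <- function() {
  list(creatinine = c(1000, 1680), albumin = c(1380, 1680),
       plsda = c(950, 1770))
}
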