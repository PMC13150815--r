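# Spectrum container and CSV I/O.

#' Construct a spectrum
#'
#' An absorbance trace (AU) on a wavenumber axis with free-form metadata.
#'
#' @param axis a `wn_axis` (or coercible numeric vector).
#' @param absorbance numeric vector, same length as `axis`, all finite.
#' @param meta named list of metadata.
#' @return object of class `ir_spectrum`.
#' @export
new_spectrum <- function(axis, absorbance, meta = list()) {
  axis <- as_wn_axis(axis)
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(axis)) {
    stop("`absorbance` and `axis` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) stop("absorbance values must be finite", call. = FALSE)
  structure(list(axis = axis, absorbance = absorbance, meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.6g-%.6g cm-1, A in [%.4g, %.4g]\n",
              length(x$axis), min(x$axis), max(x$axis),
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Resample a spectrum onto a new axis by linear interpolation
#'
#' Values at grid points shared with the source axis are unchanged;
#' extrapolation outside the source range is an error.
#'
#' @param spectrum an `ir_spectrum`.
#' @param axis target `wn_axis`.
#' @return resampled `ir_spectrum`.
#' @export
resample <- function(spectrum, axis) {
  axis <- as_wn_axis(axis)
  src <- spectrum$axis
  if (min(axis) < min(src) - 1e-9 || max(axis) > max(src) + 1e-9) {
    stop("target axis extends beyond the source range (extrapolation refused)",
         call. = FALSE)
  }
  y <- stats::approx(as.numeric(src), spectrum$absorbance,
                     xout = as.numeric(axis), method = "linear", rule = 1)$y
  new_spectrum(axis, y, meta = spectrum$meta)
}

#' Write spectra to a wide CSV (wavenumber first column)
#'
#' @param spectra a list of `ir_spectrum` sharing one axis, or a single one.
#' @param path output file. Column names come from each spectrum's
#'   `meta$name` (falling back to `spectrum_1`, ...).
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "ir_spectrum")) spectra <- list(spectra)
  axis <- spectra[[1]]$axis
  for (s in spectra) {
    if (!axes_equal(s$axis, axis)) stop("spectra must share one axis", call. = FALSE)
  }
  nms <- vapply(seq_along(spectra), function(i) {
    spectra[[i]]$meta$name %||% sprintf("spectrum_%d", i)
  }, character(1))
  m <- vapply(spectra, function(s) s$absorbance, numeric(length(axis)))
  df <- data.frame(wavenumber = as.numeric(axis), m, check.names = FALSE)
  names(df) <- c("wavenumber", nms)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from a wide CSV (wavenumber first column)
#'
#' A descending wavenumber column is accepted and normalized to ascending
#' order; the event is recorded in each spectrum's metadata
#' (`meta$axis_reversed`).
#'
#' @param path CSV file: header row of names, first column wavenumbers,
#'   remaining columns absorbance traces.
#' @return list of `ir_spectrum`.
#' @export
load_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("no absorbance columns", call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric cells in spectra CSV", call. = FALSE)
  }
  wn <- df[[1]]
  reversed <- length(wn) > 1 && all(diff(wn) < 0)
  axis <- as_wn_axis(wn)  # validates monotone/uniform, reverses if needed
  ord <- if (reversed) rev(seq_along(wn)) else seq_along(wn)
  lapply(names(df)[-1], function(nm) {
    new_spectrum(axis, df[[nm]][ord],
                 meta = list(name = nm, axis_reversed = reversed))
  })
}

# rows = spectra matrix helper used throughout the simulator/chemometrics
spectra_matrix <- function(spectra) {
  t(vapply(spectra, function(s) s$absorbance, numeric(length(spectra[[1]]$axis))))
}
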