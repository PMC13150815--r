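# Noise models: per-wavenumber Gaussian standard deviation for a given
# instrument and number of co-added scans.

new_noise_model <- function(instrument, scans, sigma, axis) {
  axis <- as_wn_axis(axis)
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(axis)) stop("`sigma` must match the axis", call. = FALSE)
  if (any(sigma < 0) || any(!is.finite(sigma))) {
    stop("`sigma` must be finite and non-negative", call. = FALSE)
  }
  structure(list(instrument = as.character(instrument),
                 scans = as.integer(scans), sigma = sigma, axis = axis),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %s, %d scan(s), median sigma %.3g AU\n",
              x$instrument, x$scans, stats::median(x$sigma)))
  invisible(x)
}

#' Estimate a noise model from replicate spectra
#'
#' Mirrors the bench procedure of acquiring the same (blank) measurement many
#' times: the per-wavenumber sample standard deviation across replicates is
#' the noise spectrum.
#'
#' @param replicates list of `ir_spectrum` (>= 2) on a common axis.
#' @param instrument id string.
#' @param scans number of co-added scans the replicates were acquired with.
#' @return a `noise_model`.
#' @export
estimate_noise_model <- function(replicates, instrument, scans) {
  if (length(replicates) < 2L) stop("need at least 2 replicates", call. = FALSE)
  axis <- replicates[[1]]$axis
  for (s in replicates) {
    if (!axes_equal(s$axis, axis)) stop("replicates must share one axis", call. = FALSE)
  }
  m <- spectra_matrix(replicates)
  sigma <- apply(m, 2, stats::sd)
  new_noise_model(instrument, scans, sigma, axis)
}

#' Parametric noise model with 1/sqrt(scans) scaling
#'
#' Synthesizes the noise library that would otherwise be measured at 1, 2, 4,
#' 8 and 10 scans: co-adding `n` scans reduces the per-wavenumber standard
#' deviation by `sqrt(n)`.
#'
#' @param instrument id string.
#' @param scans positive integer.
#' @param sigma1 noise level (AU) at 1 scan.
#' @param axis a `wn_axis`.
#' @param profile optional non-negative vector (length of `axis`) shaping the
#'   wavenumber dependence; default flat.
#' @return a `noise_model` with `sigma = sigma1 * profile / sqrt(scans)`.
#' @export
parametric_noise_model <- function(instrument, scans, sigma1, axis, profile = NULL) {
  axis <- as_wn_axis(axis)
  stopifnot_scalar_number(sigma1, "sigma1")
  if (sigma1 <= 0) stop("`sigma1` must be positive", call. = FALSE)
  if (!is.numeric(scans) || length(scans) != 1L || scans < 1) {
    stop("`scans` must be a positive integer", call. = FALSE)
  }
  profile <- profile %||% rep(1, length(axis))
  if (length(profile) != length(axis) || any(profile < 0)) {
    stop("`profile` must be non-negative and match the axis", call. = FALSE)
  }
  new_noise_model(instrument, scans, sigma1 * profile / sqrt(scans), axis)
}

#' Build a parametric noise library over instruments and scan counts
#'
#' @param instruments named numeric vector: 1-scan sigma (AU) per instrument
#'   id, e.g. `c(spectrum_two = 1e-3, spectrum_3 = 8e-4)`.
#' @param scans_levels integer vector of scan counts.
#' @param axis a `wn_axis`.
#' @param profile optional shared wavenumber profile.
#' @return nested list `library[[instrument]][[as.character(scans)]]`.
#' @export
noise_library <- function(instruments = c(spectrum_two = 1e-3, spectrum_3 = 8e-4),
                          scans_levels = c(1, 2, 4, 8, 10),
                          axis = make_axis(450, 4000, 2),
                          profile = NULL) {
  lib <- lapply(names(instruments), function(ins) {
    models <- lapply(scans_levels, function(sc) {
      parametric_noise_model(ins, sc, instruments[[ins]], axis, profile)
    })
    names(models) <- as.character(scans_levels)
    models
  })
  names(lib) <- names(instruments)
  structure(lib, class = "noise_library")
}

get_noise_model <- function(noise_lib, instrument, scans) {
  if (inherits(noise_lib, "noise_model")) return(noise_lib)
  m <- noise_lib[[instrument]][[as.character(scans)]]
  if (is.null(m)) {
    stop(sprintf("no noise model for instrument '%s' at %s scan(s)",
                 instrument, scans), call. = FALSE)
  }
  m
}
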