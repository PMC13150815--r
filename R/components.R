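# Pure-component standards: synthetic Gaussian-band stand-ins for measured
# aqueous standards, plus the water spectrum fixture.

#' Describe one absorption band
#'
#' @param center band center in cm-1.
#' @param fwhm full width at half maximum in cm-1 (> 0).
#' @param height peak absorbance (AU) contributed at the component's standard
#'   concentration (>= 0).
#' @return object of class `band_model`.
#' @export
band_model <- function(center, fwhm, height) {
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(fwhm, "fwhm")
  stopifnot_scalar_number(height, "height")
  if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  if (height < 0) stop("`height` must be non-negative", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, height = height),
            class = "band_model")
}

# Gaussian profile parameterized by FWHM.
gaussian_band <- function(axis, center, fwhm, height) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-((as.numeric(axis) - center)^2) / (2 * sigma^2))
}

#' Synthetic water spectrum fixture
#'
#' Broad O-H stretching (~3400 cm-1) and bending (~1640 cm-1) bands plus a
#' low-wavenumber libration shoulder and a small constant offset. The exact
#' shape is a fixture choice: what matters downstream is that water dominates
#' the raw spectrum and carries no analyte information.
#'
#' @param axis a `wn_axis`.
#' @return an `ir_spectrum` named `"water"`.
#' @export
water_spectrum <- function(axis = make_axis(450, 4000, 2)) {
  axis <- as_wn_axis(axis)
  a <- gaussian_band(axis, 3400, 500, 0.45) +
    gaussian_band(axis, 1640, 120, 0.35) +
    gaussian_band(axis, 640, 350, 0.25) + 0.01
  new_spectrum(axis, a, meta = list(name = "water"))
}

#' Synthesize a pure-component standard
#'
#' Builds the aqueous-standard spectrum `b_i` as the water spectrum plus a sum
#' of Gaussian bands, at the standard concentration `s`. Components of class
#' `non_absorbing_salt` carry no bands of their own (their spectrum equals
#' water); a small perturbation of the water bands can be injected through
#' `salt_water_perturbation`.
#'
#' @param name component name (unique within a library).
#' @param bands list of `band_model` (possibly empty).
#' @param s standard concentration in mg/L (> 0).
#' @param axis a `wn_axis`.
#' @param water the water `ir_spectrum` on the same axis.
#' @param mol_class one of `"protein"`, `"low_mw"`, `"non_absorbing_salt"`,
#'   `"contaminant"`.
#' @param salt_water_perturbation optional numeric vector (length of axis)
#'   added to the water contribution, for salts that reshape the water bands.
#' @return object of class `component_standard` with fields `name`,
#'   `standard_concentration`, `spectrum`, `mol_class`.
#' @export
synth_component <- function(name, bands, s, axis, water,
                            mol_class = c("low_mw", "protein",
                                          "non_absorbing_salt", "contaminant"),
                            salt_water_perturbation = NULL) {
  mol_class <- match.arg(mol_class)
  stopifnot_scalar_number(s, "s")
  if (s <= 0) stop("standard concentration `s` must be positive", call. = FALSE)
  axis <- as_wn_axis(axis)
  if (!axes_equal(water$axis, axis)) stop("water must be on the same axis", call. = FALSE)
  a <- water$absorbance
  if (!is.null(salt_water_perturbation)) {
    if (length(salt_water_perturbation) != length(axis)) {
      stop("`salt_water_perturbation` must match the axis", call. = FALSE)
    }
    a <- a + salt_water_perturbation
  }
  for (b in bands) {
    if (b$center < min(axis) || b$center > max(axis)) {
      warning(sprintf("band center %.1f cm-1 of '%s' lies outside the axis; clipped",
                      b$center, name), call. = FALSE)
      next
    }
    a <- a + gaussian_band(axis, b$center, b$fwhm, b$height)
  }
  structure(list(name = as.character(name), standard_concentration = s,
                 spectrum = new_spectrum(axis, a, meta = list(name = name)),
                 mol_class = mol_class),
            class = "component_standard")
}

#' @export
print.component_standard <- function(x, ...) {
  cat(sprintf("<component_standard> %s (%s), s = %.4g mg/L\n",
              x$name, x$mol_class, x$standard_concentration))
  invisible(x)
}

#' Packaged component table (concentration ranges and classes)
#'
#' The 13 urine components with their calibration ranges (mg/L), literature
#' reference ranges, molecular class, and the standard concentration at which
#' the synthetic pure-component spectrum is defined (about ten times the
#' reference-range midpoint, mirroring high-concentration standards measured
#' to maximize signal-to-noise ratio).
#'
#' @return data.frame with columns `name`, `mol_class`, `standard_conc`,
#'   `cal_min`, `cal_max`, `ref_min`, `ref_max`.
#' @export
component_table <- function() {
  utils::read.csv(system.file("extdata", "components.csv", package = "uirsim"),
                  stringsAsFactors = FALSE)
}

#' Packaged synthetic band table
#'
#' Gaussian band parameters (center, FWHM, peak height at the standard
#' concentration) for every absorbing component. Centers of the prominent
#' urine bands (urea 1626/1599/1466, sulfate 1100, phosphate 1080 cm-1,
#' albumin amide II near 1548 cm-1) follow their accepted positions; widths
#' and heights are editable fixture choices.
#'
#' @return data.frame with columns `component`, `center`, `fwhm`, `height`.
#' @export
band_table <- function() {
  utils::read.csv(system.file("extdata", "bands.csv", package = "uirsim"),
                  stringsAsFactors = FALSE)
}

#' Build the default 13-component synthetic spectral library
#'
#' @param axis a `wn_axis`.
#' @param components optional component table (see [component_table()]).
#' @param bands optional band table (see [band_table()]).
#' @return object of class `spectral_library`: list with `components` (named
#'   list of `component_standard`), `water` and `axis`.
#' @export
default_component_library <- function(axis = make_axis(450, 4000, 2),
                                      components = component_table(),
                                      bands = band_table()) {
  axis <- as_wn_axis(axis)
  water <- water_spectrum(axis)
  comps <- lapply(seq_len(nrow(components)), function(i) {
    row <- components[i, ]
    b <- bands[bands$component == row$name, , drop = FALSE]
    blist <- lapply(seq_len(nrow(b)), function(j) {
      band_model(b$center[j], b$fwhm[j], b$height[j])
    })
    synth_component(row$name, blist, row$standard_conc, axis, water,
                    mol_class = row$mol_class)
  })
  names(comps) <- components$name
  if (anyDuplicated(components$name)) stop("component names must be unique", call. = FALSE)
  structure(list(components = comps, water = water, axis = axis),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d components on %d axis points\n",
              length(x$components), length(x$axis)))
  invisible(x)
}

library_classes <- function(library) {
  vapply(library$components, `[[`, character(1), "mol_class")
}
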