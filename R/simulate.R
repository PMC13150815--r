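# Mixture-model spectral simulation: each sample spectrum is a linear
# combination of pure-component standard spectra plus water and additive
# per-wavenumber Gaussian noise.

# solute contribution matrix (components x wavenumbers) and c/s ratios
.mixture_parts <- function(conc_row, library) {
  nz <- names(conc_row)[conc_row > 0]
  missing_comp <- setdiff(nz, names(library$components))
  if (length(missing_comp)) {
    stop(sprintf("no library entry for component(s): %s",
                 paste(missing_comp, collapse = ", ")), call. = FALSE)
  }
  comps <- library$components[names(conc_row)[names(conc_row) %in% names(library$components)]]
  ratios <- conc_row[names(comps)] /
    vapply(comps, `[[`, numeric(1), "standard_concentration")
  if (any(ratios > 1)) {
    warning(sprintf("concentration above the standard for: %s (extrapolating)",
                    paste(names(comps)[ratios > 1], collapse = ", ")),
            call. = FALSE)
  }
  B <- t(vapply(comps, function(cc) cc$spectrum$absorbance,
                numeric(length(library$axis))))
  list(ratios = as.numeric(ratios), B = B)
}

#' Simulate one sample spectrum from its component concentrations
#'
#' The mixture model sums, for each of the `n` components, the standard
#' spectrum `b_i` scaled by the concentration ratio `c_i / s_i` plus the water
#' spectrum scaled by `(1 - c_i / s_i)`, then adds zero-mean Gaussian noise
#' with the per-wavenumber standard deviation of the noise model:
#' `A_j = sum_i [ (c_i/s_i) b_ij + (1 - c_i/s_i) w_j ] + N(0, sigma_j)`.
#'
#' Two water conventions are exposed. `"verbatim"` (default) accumulates one
#' water term per component as written above, so an all-zero blank equals `n`
#' times the water spectrum; the constant offset is removed downstream by
#' baseline/SNV preprocessing. `"single_water"` uses the physically normalized
#' form `sum_i (c_i/s_i)(b_ij - w_j) + w_j`, which keeps a single water
#' contribution.
#'
#' @param conc_row named numeric vector of concentrations (mg/L); every
#'   nonzero entry must have a library component.
#' @param library a `spectral_library`.
#' @param noise_model a `noise_model` on the same axis, or `NULL` for
#'   noise-free simulation.
#' @param mode `"verbatim"` or `"single_water"`.
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_model` is `NULL`).
#' @return an `ir_spectrum`.
#' @export
simulate_spectrum <- function(conc_row, library, noise_model = NULL,
                              mode = c("verbatim", "single_water"), seed = 1) {
  mode <- match.arg(mode)
  parts <- .mixture_parts(conc_row, library)
  w <- library$water$absorbance
  solute <- drop(crossprod(parts$B, parts$ratios))
  a <- if (mode == "verbatim") {
    solute + sum(1 - parts$ratios) * w
  } else {
    solute - sum(parts$ratios) * w + w
  }
  if (!is.null(noise_model)) {
    if (!axes_equal(noise_model$axis, library$axis)) {
      stop("noise model axis differs from the library axis", call. = FALSE)
    }
    set.seed(seed)
    a <- a + stats::rnorm(length(a)) * noise_model$sigma
  }
  new_spectrum(library$axis, a, meta = list(mode = mode))
}

#' Urinary albumin-to-creatinine ratio
#'
#' `UACR = albumin [mg/L] / (creatinine [g/L])` in mg/g; samples with
#' `UACR >= 30` mg/g are flagged albuminuric (UACR < 30 is normoalbuminuric).
#'
#' @param albumin,creatinine concentrations in mg/L (creatinine > 0).
#' @return data.frame with columns `uacr` (mg/g) and `albuminuric` (logical).
#' @export
compute_uacr <- function(albumin, creatinine) {
  if (any(creatinine <= 0)) stop("creatinine must be positive", call. = FALSE)
  uacr <- albumin / (creatinine / 1000)
  data.frame(uacr = uacr, albuminuric = uacr >= 30)
}

#' Simulate a complete dataset under one pretreatment condition
#'
#' Applies the pretreatment to the nominal design, then builds one spectrum
#' per run with additive instrument noise. Randomness is drawn from
#' sample-indexed streams derived from `seed`: the standard-normal noise
#' matrix depends only on `seed` (so two conditions sharing an instrument and
#' scan count receive identical noise realizations), and the
#' preconcentration-error quantiles depend only on `seed` (so all conditions
#' share them). UACR labels are computed from the nominal (pre-pretreatment)
#' albumin and creatinine concentrations.
#'
#' @param design a `conc_design` (nominal, pre-pretreatment).
#' @param condition a `pretreatment_condition`.
#' @param library a `spectral_library`.
#' @param noise_lib a `noise_library` (or a single `noise_model`); `NULL`
#'   disables noise.
#' @param seed integer master seed.
#' @param mode water convention, see [simulate_spectrum()].
#' @return object of class `sim_dataset`: `spectra` (runs x wavenumbers),
#'   `axis`, `concentrations` (post-pretreatment `conc_design`),
#'   `nominal` (input design), `condition`, `labels` (UACR data.frame, when
#'   albumin and creatinine are among the components), `realized_factors`,
#'   `seed`.
#' @export
simulate_dataset <- function(design, condition, library,
                             noise_lib = noise_library(axis = library$axis),
                             seed = 1, mode = c("verbatim", "single_water")) {
  mode <- match.arg(mode)
  n <- nrow(design$concentrations)
  p <- length(library$axis)
  treated <- apply_pretreatment(design, condition, library,
                                seed = derive_seed(seed, "preconc"))
  noise_model <- if (!is.null(noise_lib)) {
    get_noise_model(noise_lib, condition$instrument, condition$scans)
  }
  set.seed(derive_seed(seed, "noise"))
  Z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  spectra <- matrix(0, n, p)
  for (i in seq_len(n)) {
    conc_row <- treated$concentrations[i, ]
    names(conc_row) <- colnames(treated$concentrations)
    s <- simulate_spectrum(conc_row, library, noise_model = NULL, mode = mode)
    spectra[i, ] <- s$absorbance
  }
  if (!is.null(noise_model)) {
    spectra <- spectra + Z * rep(noise_model$sigma, each = n)
  }
  colnames(spectra) <- as.numeric(library$axis)
  labels <- NULL
  comp <- colnames(design$concentrations)
  if (all(c("albumin", "creatinine") %in% comp)) {
    labels <- compute_uacr(design$concentrations[, "albumin"],
                           design$concentrations[, "creatinine"])
  }
  structure(list(spectra = spectra, axis = library$axis,
                 concentrations = treated, nominal = design,
                 condition = condition, labels = labels,
                 realized_factors = treated$realized_factors, seed = seed,
                 mode = mode),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d spectra x %d wavenumbers (%gx, %d step(s), %d scan(s), %s)\n",
              nrow(x$spectra), ncol(x$spectra), x$condition$preconc_nominal,
              x$condition$cleaning_steps, x$condition$scans,
              x$condition$instrument))
  invisible(x)
}

#' Subtract the water contribution from a spectrum
#'
#' `mode = "unit"` subtracts the water spectrum once; `mode = "fit"` subtracts
#' `k * w` with `k` chosen by least squares over a solute-free window
#' (default 1900-2600 cm-1), reporting `k` in the result's metadata.
#'
#' @param spectrum an `ir_spectrum`.
#' @param water the water `ir_spectrum` on the same axis.
#' @param mode `"unit"` or `"fit"`.
#' @param window numeric length-2 fitting window in cm-1 (fit mode).
#' @return an `ir_spectrum`; in fit mode `meta$water_scale` holds `k`.
#' @export
subtract_water <- function(spectrum, water, mode = c("unit", "fit"),
                           window = c(1900, 2600)) {
  mode <- match.arg(mode)
  if (!axes_equal(spectrum$axis, water$axis)) {
    stop("spectrum and water must share one axis", call. = FALSE)
  }
  if (mode == "unit") {
    return(new_spectrum(spectrum$axis, spectrum$absorbance - water$absorbance,
                        meta = spectrum$meta))
  }
  v <- as.numeric(spectrum$axis)
  sel <- v >= min(window) & v <= max(window)
  if (!any(sel)) stop("empty water-fit window", call. = FALSE)
  k <- sum(spectrum$absorbance[sel] * water$absorbance[sel]) /
    sum(water$absorbance[sel]^2)
  meta <- spectrum$meta
  meta$water_scale <- k
  new_spectrum(spectrum$axis, spectrum$absorbance - k * water$absorbance, meta)
}
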