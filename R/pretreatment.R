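# Simulated sample pretreatment: protein preconcentration by ultrafiltration
# (stochastic fold factor) and cleaning steps that dilute low-molecular-weight
# metabolites.

#' Describe one pretreatment / acquisition condition
#'
#' @param preconc_nominal nominal protein preconcentration fold (>= 1;
#'   typical grid: 1, 25, 50, 100).
#' @param preconc_cv coefficient of variation of the realized fold factor
#'   (default 0.15, the irreproducibility of the retentate volume).
#' @param cleaning_steps number of post-concentration wash/re-spin steps
#'   (>= 0); each multiplies low-molecular-weight and salt concentrations by
#'   `per_step_dilution`.
#' @param per_step_dilution dilution per cleaning step (default 0.05, so two
#'   steps give 0.0025).
#' @param scans number of co-added scans (>= 1).
#' @param instrument instrument id (must match the noise library).
#' @return object of class `pretreatment_condition`.
#' @export
pretreatment_condition <- function(preconc_nominal = 1, preconc_cv = 0.15,
                                   cleaning_steps = 0, per_step_dilution = 0.05,
                                   scans = 10, instrument = "spectrum_two") {
  if (preconc_nominal < 1) stop("`preconc_nominal` must be >= 1", call. = FALSE)
  if (preconc_cv < 0 || preconc_cv >= 1) stop("`preconc_cv` must be in [0, 1)", call. = FALSE)
  if (cleaning_steps < 0) stop("`cleaning_steps` must be >= 0", call. = FALSE)
  if (per_step_dilution <= 0 || per_step_dilution > 1) {
    stop("`per_step_dilution` must be in (0, 1]", call. = FALSE)
  }
  if (scans < 1) stop("`scans` must be >= 1", call. = FALSE)
  structure(list(preconc_nominal = preconc_nominal, preconc_cv = preconc_cv,
                 cleaning_steps = as.integer(cleaning_steps),
                 per_step_dilution = per_step_dilution,
                 scans = as.integer(scans),
                 instrument = as.character(instrument)),
            class = "pretreatment_condition")
}

#' @export
print.pretreatment_condition <- function(x, ...) {
  cat(sprintf("<pretreatment_condition> %gx preconc (cv %.0f%%), %d cleaning step(s), %d scan(s), %s\n",
              x$preconc_nominal, 100 * x$preconc_cv, x$cleaning_steps,
              x$scans, x$instrument))
  invisible(x)
}

#' Draw realized preconcentration fold factors
#'
#' One draw per sample from `Normal(nominal, cv * nominal)`, truncated below
#' at 1% of the nominal factor (truncation events are counted in the
#' `"n_truncated"` attribute).
#'
#' @param condition a `pretreatment_condition`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
draw_preconc_factors <- function(condition, n, seed) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  mu <- condition$preconc_nominal
  sd <- condition$preconc_cv * mu
  set.seed(seed)
  f <- stats::rnorm(n, mean = 0, sd = 1)  # standard stream, shared quantiles
  f <- mu + sd * f
  floor_ <- 0.01 * mu
  n_trunc <- sum(f < floor_)
  f[f < floor_] <- floor_
  attr(f, "n_truncated") <- n_trunc
  f
}

#' Apply a pretreatment condition to a concentration design
#'
#' Protein-class components are multiplied by the per-sample realized
#' preconcentration factor; low-molecular-weight metabolites and
#' non-absorbing salts pass the 10 kDa membrane and are only affected by
#' cleaning steps, each of which dilutes them by `per_step_dilution`.
#'
#' @param design a `conc_design`.
#' @param condition a `pretreatment_condition`.
#' @param library a `spectral_library` (supplies each component's class).
#' @param seed integer seed for the realized factors.
#' @param factors optional pre-drawn realized factors (overrides `seed`),
#'   length = runs.
#' @return a `conc_design` with provenance suffix `"+pretreated"`, carrying
#'   `realized_factors` and the input design as `nominal`.
#' @export
apply_pretreatment <- function(design, condition, library, seed = 1,
                               factors = NULL) {
  conc <- design$concentrations
  classes <- library_classes(library)
  missing_cls <- setdiff(colnames(conc), names(classes))
  if (length(missing_cls)) {
    stop(sprintf("component(s) with unknown class: %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  }
  cls <- classes[colnames(conc)]
  if (is.null(factors)) {
    factors <- draw_preconc_factors(condition, nrow(conc), seed)
  }
  if (length(factors) != nrow(conc)) {
    stop("`factors` must have one entry per run", call. = FALSE)
  }
  dil <- condition$per_step_dilution^condition$cleaning_steps
  out <- conc
  is_protein <- cls == "protein"
  is_small <- cls %in% c("low_mw", "non_absorbing_salt", "contaminant")
  out[, is_protein] <- conc[, is_protein, drop = FALSE] * factors
  out[, is_small] <- conc[, is_small, drop = FALSE] * dil
  new_conc_design(out, provenance = paste0(design$provenance, "+pretreated"),
                  extra = list(realized_factors = as.numeric(factors),
                               nominal = design, condition = condition))
}
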