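# Seven-level mutually orthogonal calibration design and sampled
# (optionally correlated) concentration sets.

# 49-entry base sequence over coded levels -3..3 (each level 7 times).
# Columns of the design are cyclic rotations of this sequence, so the
# correlation between any two factors equals its circular autocorrelation at
# the lag separating them. The sequence was selected once, by a deterministic
# offline search over level permutations, to minimize the maximum absolute
# circular autocorrelation over lags 1-12; the frozen optimum reaches
# max |r| = 3/196 ~ 0.0153.
.brereton_base <- as.integer(c(2, 2, 1, -2, 0, 1, 3, -2, 2, 2, 0, -1, 2, -3,
                               2, -3, 0, 3, 1, 3, -1, -3, 1, 3, 0, -1, 1, -1,
                               -3, -2, -2, 1, -3, -1, -3, -2, 3, 3, -2, 1, 0,
                               -1, -3, 0, 0, -2, 2, -1, 3))

#' Generate the 49-run seven-level (near-)orthogonal design
#'
#' Coded levels are `-3 ... +3`; each level appears exactly 7 times in every
#' column, and every pair of columns has |Pearson correlation| <= `tol`
#' (verified at construction). Columns are cyclic rotations of a fixed base
#' sequence, recorded in the result's metadata, so generation is
#' deterministic.
#'
#' @param n_factors number of components (1 to 13).
#' @param n_runs number of mixtures; only 49 is supported.
#' @param tol orthogonality tolerance on pairwise column correlations.
#' @return object of class `level_design`: list with `levels` (49 x
#'   `n_factors` integer matrix), `n_levels = 7`, and `base_sequence`.
#' @export
brereton_design <- function(n_factors, n_runs = 49, tol = 0.05) {
  if (n_runs != 49) stop("only the 49-run seven-level design is supported", call. = FALSE)
  if (!is.numeric(n_factors) || length(n_factors) != 1L ||
      n_factors < 1 || n_factors > 13) {
    stop("`n_factors` must be between 1 and 13", call. = FALSE)
  }
  n_factors <- as.integer(n_factors)
  base <- .brereton_base
  m <- vapply(seq_len(n_factors), function(f) {
    rot <- ((seq_len(49) - 1 + (f - 1)) %% 49) + 1
    base[rot]
  }, integer(49))
  m <- matrix(m, nrow = 49, ncol = n_factors)
  d <- structure(list(levels = m, n_levels = 7L, base_sequence = base),
                 class = "level_design")
  rep_ <- orthogonality_report(d)
  if (rep_$max_abs_correlation > tol) {
    stop(sprintf("design construction failed: max |r| = %.4f > %.4f",
                 rep_$max_abs_correlation, tol), call. = FALSE)
  }
  d
}

#' @export
print.level_design <- function(x, ...) {
  cat(sprintf("<level_design> %d runs x %d factors, %d levels\n",
              nrow(x$levels), ncol(x$levels), x$n_levels))
  invisible(x)
}

#' Orthogonality diagnostics of a level design
#'
#' @param design a `level_design`.
#' @return list with `max_abs_correlation` (0 for a single column),
#'   `correlations` (factor-pair matrix) and `level_counts` (levels x factors
#'   count table).
#' @export
orthogonality_report <- function(design) {
  m <- design$levels
  counts <- apply(m, 2, function(col) table(factor(col, levels = -3:3)))
  if (ncol(m) >= 2) {
    r <- stats::cor(m)
    diag(r) <- 0
    maxr <- max(abs(r))
  } else {
    r <- matrix(0, 1, 1)
    maxr <- 0
  }
  list(max_abs_correlation = maxr, correlations = r, level_counts = counts)
}

#' Component concentration range
#'
#' @param name component name.
#' @param cal_min,cal_max calibration range in mg/L (`cal_min >= 0`,
#'   `cal_max > cal_min`).
#' @return object of class `component_range`.
#' @export
component_range <- function(name, cal_min, cal_max) {
  stopifnot_scalar_number(cal_min, "cal_min")
  stopifnot_scalar_number(cal_max, "cal_max")
  if (cal_min < 0) stop("`cal_min` must be non-negative", call. = FALSE)
  if (cal_max <= cal_min) stop("`cal_max` must exceed `cal_min`", call. = FALSE)
  structure(list(name = as.character(name), cal_min = cal_min, cal_max = cal_max),
            class = "component_range")
}

#' Packaged default calibration ranges
#'
#' @return named list of `component_range`, one per packaged component.
#' @export
default_ranges <- function() {
  tab <- component_table()
  rngs <- lapply(seq_len(nrow(tab)), function(i) {
    component_range(tab$name[i], tab$cal_min[i], tab$cal_max[i])
  })
  names(rngs) <- tab$name
  rngs
}

#' Map coded levels to concentrations
#'
#' Level `l` in `-3 ... +3` maps affinely onto the component's calibration
#' range: `conc = cal_min + (l + 3) / 6 * (cal_max - cal_min)`, so levels -3
#' and +3 hit the range endpoints exactly.
#'
#' @param design a `level_design`.
#' @param ranges list of `component_range`, one per factor (in column order).
#' @return object of class `conc_design`: list with `concentrations` (runs x
#'   components matrix, mg/L), `components` (names) and `provenance`.
#' @export
levels_to_concentrations <- function(design, ranges) {
  m <- design$levels
  if (length(ranges) != ncol(m)) {
    stop("need exactly one range per design factor", call. = FALSE)
  }
  conc <- vapply(seq_along(ranges), function(j) {
    r <- ranges[[j]]
    r$cal_min + (m[, j] + 3) / 6 * (r$cal_max - r$cal_min)
  }, numeric(nrow(m)))
  conc <- matrix(conc, nrow = nrow(m))
  colnames(conc) <- vapply(ranges, `[[`, character(1), "name")
  new_conc_design(conc, provenance = "orthogonal_design")
}

new_conc_design <- function(conc, provenance, extra = list(),
                            check_nonneg = TRUE) {
  if (check_nonneg && any(conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(c(list(concentrations = conc,
                   components = colnames(conc),
                   provenance = provenance), extra),
            class = "conc_design")
}

#' @export
print.conc_design <- function(x, ...) {
  cat(sprintf("<conc_design> %d runs x %d components (%s)\n",
              nrow(x$concentrations), ncol(x$concentrations), x$provenance))
  invisible(x)
}

#' Sample concentrations from a correlated multivariate normal
#'
#' Draws `n` samples with the given per-component means/SDs and correlation
#' matrix; negative draws are truncated to zero when `truncate_at_zero` (the
#' count of truncation events is recorded in the result as `n_truncated`).
#'
#' @param means,sds named numeric vectors (mg/L), equal lengths.
#' @param corr_matrix correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite); default identity.
#' @param n number of samples.
#' @param seed integer seed (draws are reproducible).
#' @param truncate_at_zero logical, default TRUE.
#' @return a `conc_design` with provenance `"sampled"`.
#' @export
sample_concentrations <- function(means, sds, corr_matrix = NULL, n, seed,
                                  truncate_at_zero = TRUE) {
  p <- length(means)
  if (length(sds) != p) stop("`means` and `sds` lengths differ", call. = FALSE)
  corr_matrix <- corr_matrix %||% diag(p)
  if (!isTRUE(all.equal(dim(corr_matrix), c(p, p)))) {
    stop("correlation matrix dimension mismatch", call. = FALSE)
  }
  if (max(abs(corr_matrix - t(corr_matrix))) > 1e-8 ||
      max(abs(diag(corr_matrix) - 1)) > 1e-8) {
    stop("correlation matrix must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite", call. = FALSE)
  sigma <- diag(sds, p) %*% corr_matrix %*% diag(sds, p)
  set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = means, Sigma = sigma)
  draws <- matrix(draws, nrow = n)
  n_trunc <- 0L
  if (truncate_at_zero) {
    n_trunc <- sum(draws < 0)
    draws[draws < 0] <- 0
  }
  colnames(draws) <- names(means) %||% sprintf("component_%d", seq_len(p))
  new_conc_design(draws, provenance = "sampled",
                  extra = list(n_truncated = n_trunc, seed = seed),
                  check_nonneg = truncate_at_zero)
}

#' Placeholder correlation matrix for sampled urine concentrations
#'
#' Urea, creatinine, sulfate and phosphate excretion all scale with urine
#' concentration (hydration), so they are sampled with positive mutual
#' correlations. The packaged values are PLACEHOLDERS chosen as physiologically
#' plausible defaults, not measured values; override them for any quantitative
#' use.
#'
#' @param components character vector of component names (defaults to the
#'   packaged 13).
#' @return correlation matrix with unit diagonal.
#' @export
default_concentration_correlations <- function(components = component_table()$name) {
  p <- length(components)
  corr <- diag(p)
  dimnames(corr) <- list(components, components)
  grp <- c("urea", "creatinine", "Na2SO4", "MgSO4", "NaH2PO4")
  grp <- intersect(grp, components)
  vals <- c(urea = 0.65, creatinine = 0.6, Na2SO4 = 0.55, MgSO4 = 0.5,
            NaH2PO4 = 0.55)
  for (a in grp) for (b in grp) {
    if (a != b) corr[a, b] <- min(vals[[a]], vals[[b]])
  }
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > 0)
  corr
}
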