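# End-to-end in silico experiments: the pretreatment/acquisition optimization
# grid, Monte Carlo double cross-validation, and in silico calibration.

#' Factorial grid of pretreatment/acquisition conditions
#'
#' @param preconc preconcentration folds (default 1, 25, 50, 100).
#' @param cleaning cleaning-step counts (default 0, 1, 2).
#' @param scans scan counts (default 1, 2, 4, 8, 10).
#' @param instruments instrument ids (default `"spectrum_two"`).
#' @param preconc_cv coefficient of variation of the fold factor.
#' @return list of `pretreatment_condition`, full factorial coverage.
#' @export
grid_conditions <- function(preconc = c(1, 25, 50, 100), cleaning = 0:2,
                            scans = c(1, 2, 4, 8, 10),
                            instruments = "spectrum_two", preconc_cv = 0.15) {
  g <- expand.grid(preconc = preconc, cleaning = cleaning, scans = scans,
                   instrument = instruments, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    pretreatment_condition(preconc_nominal = g$preconc[i],
                           preconc_cv = preconc_cv,
                           cleaning_steps = g$cleaning[i],
                           scans = g$scans[i], instrument = g$instrument[i])
  })
}

#' Run the condition-grid optimization
#'
#' For every condition, simulates the dataset (seed reset per condition, so
#' noise realizations and preconcentration-error quantiles are shared across
#' conditions), applies the per-spectrum preprocessing chain, selects each
#' analyte's region, and records the venetian-blinds RMSECV at the
#' RMSECV-minimizing LV count. The response is the analyte's nominal
#' (pre-pretreatment) concentration, so RMSECV is on the original urine scale
#' and comparable across conditions.
#'
#' @param design a nominal `conc_design`.
#' @param library a `spectral_library`.
#' @param conditions list of `pretreatment_condition` (see
#'   [grid_conditions()]).
#' @param analytes named list mapping analyte (a design component) to its
#'   region `c(lo, hi)`; defaults to creatinine and albumin fingerprint
#'   windows.
#' @param seed master seed (reused for every condition).
#' @param noise_lib a `noise_library`.
#' @param max_lv maximum LVs assessed in CV.
#' @param k CV folds.
#' @return data.frame (class `grid_result`) with one row per condition x
#'   analyte: condition descriptors, `rmsecv`, `r2cv`, `n_lv` (RMSECV
#'   minimum), `n_lv_incremental`, and `seed`.
#' @export
run_grid <- function(design, library, conditions,
                     analytes = list(creatinine = c(1000, 1680),
                                     albumin = c(1380, 1680)),
                     seed = 1,
                     noise_lib = noise_library(axis = library$axis),
                     max_lv = 10, k = 10) {
  if (length(conditions) == 0) stop("empty condition set", call. = FALSE)
  rows <- list()
  for (cond in conditions) {
    ds <- suppressWarnings(
      simulate_dataset(design, cond, library, noise_lib, seed = seed)
    )
    pre <- preprocess_spectra(ds$spectra, ds$axis)
    for (an in names(analytes)) {
      Xr <- select_region(pre, attr(pre, "axis"),
                          analytes[[an]][1], analytes[[an]][2])
      y <- design$concentrations[, an]
      cv <- venetian_cv(Xr, y, max_lv = max_lv, k = k)
      lv <- select_lv_min(cv)
      rows[[length(rows) + 1]] <- data.frame(
        instrument = cond$instrument, preconc = cond$preconc_nominal,
        cleaning_steps = cond$cleaning_steps, scans = cond$scans,
        analyte = an, rmsecv = cv$rmsecv[lv],
        r2cv = r2(cv$predictions[, lv], y),
        n_lv = lv, n_lv_incremental = select_lv_incremental(cv),
        seed = seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", class(out))
  out
}

#' Monte Carlo double cross-validation
#'
#' Repeated random train/test splitting. Within each split, venetian-blinds
#' CV on the training rows selects the LV count (incremental rule by
#' default), the model is refitted on the full training set, and the
#' held-out rows are scored: RMSEP for regression, AUROC plus
#' misclassification fraction for classification. The split sequence is a
#' pure function of `(seed, n_rows)`, so two datasets with equal row counts
#' share identical splits. Classification splits that leave a single class
#' in the training or test rows are redrawn from a derived sub-seed (the
#' redraw count is reported).
#'
#' @param X predictor matrix.
#' @param y numeric response (regression) or binary labels (classification;
#'   pass logicals or a 2-level factor).
#' @param n_splits number of random splits, default 100.
#' @param test_fraction fraction of rows held out per split (0, 1), default
#'   0.30.
#' @param seed master seed.
#' @param lv_rule `"incremental"` (default) or `"min"`.
#' @param max_lv,k inner-CV settings.
#' @return object of class `mc2cv_result`: `task`, per-split `rmsep` or
#'   `auroc`/`class_error`, `n_lv` per split, `splits` (list of test index
#'   vectors), `n_redrawn`.
#' @export
mc2cv <- function(X, y, n_splits = 100, test_fraction = 0.30, seed = 1,
                  lv_rule = c("incremental", "min"), max_lv = 10, k = 10) {
  lv_rule <- match.arg(lv_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  classification <- is.logical(y) || is.factor(y)
  yb <- if (classification) as_binary_labels(y) else as.numeric(y)
  n_test <- max(1, round(test_fraction * n))
  if (n_test >= n) stop("test fraction leaves no training rows", call. = FALSE)
  pick <- function(s) which(seq_len(n) %in% s)
  select_lv <- function(cv) {
    if (lv_rule == "incremental") select_lv_incremental(cv) else select_lv_min(cv)
  }
  splits <- vector("list", n_splits)
  n_redrawn <- 0L
  for (s in seq_len(n_splits)) {
    attempt <- 0L
    repeat {
      set.seed(derive_seed(seed, "mc2cv", n, s, attempt))
      test <- sort(sample.int(n, n_test))
      if (!classification) break
      ok <- length(unique(yb[test])) == 2 && length(unique(yb[-test])) == 2
      if (ok) break
      attempt <- attempt + 1L
      n_redrawn <- n_redrawn + 1L
      if (attempt > 100L) stop("could not draw a two-class split", call. = FALSE)
    }
    splits[[s]] <- test
  }
  rmsep <- numeric(n_splits); auc <- numeric(n_splits)
  cerr <- numeric(n_splits); lvs <- integer(n_splits)
  for (s in seq_len(n_splits)) {
    test <- splits[[s]]
    Xtr <- X[-test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    cv <- venetian_cv(Xtr, yb[-test], max_lv = max_lv, k = min(k, nrow(Xtr)))
    lv <- min(select_lv(cv), cv$max_lv)
    lvs[s] <- lv
    if (classification) {
      fit <- fit_plsda(Xtr, yb[-test] == 1, lv)
      sc <- predict(fit$model, Xte)
      auc[s] <- auroc(sc, yb[test] == 1)
      cerr[s] <- classification_error(sc >= fit$threshold, yb[test] == 1)
    } else {
      fit <- fit_pls(Xtr, yb[-test], lv)
      rmsep[s] <- rmse(predict(fit, Xte), yb[test])
    }
  }
  out <- list(task = if (classification) "classification" else "regression",
              n_lv = lvs, splits = splits, n_redrawn = n_redrawn,
              n_splits = n_splits, test_fraction = test_fraction, seed = seed)
  if (classification) {
    out$auroc <- auc; out$class_error <- cerr
  } else {
    out$rmsep <- rmsep
  }
  structure(out, class = "mc2cv_result")
}

#' @export
print.mc2cv_result <- function(x, ...) {
  if (x$task == "regression") {
    cat(sprintf("<mc2cv_result> %d splits, RMSEP %.4g +/- %.4g\n",
                x$n_splits, mean(x$rmsep), stats::sd(x$rmsep)))
  } else {
    cat(sprintf("<mc2cv_result> %d splits, AUROC %.3f +/- %.3f, error %.3f\n",
                x$n_splits, mean(x$auroc), stats::sd(x$auroc),
                mean(x$class_error)))
  }
  invisible(x)
}

#' Compare two metric distributions
#'
#' Two-sided Welch t test or Wilcoxon rank-sum test on two vectors of
#' performance values (e.g. MC2CV RMSEP distributions).
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param test `"welch_t"` or `"wilcoxon_ranksum"`.
#' @return list with `statistic`, `p_value`, `test`.
#' @export
compare_distributions <- function(a, b, test = c("welch_t", "wilcoxon_ranksum")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample must contain at least 2 values", call. = FALSE)
  }
  ht <- if (test == "welch_t") {
    stats::t.test(a, b, var.equal = FALSE)
  } else {
    stats::wilcox.test(a, b, exact = FALSE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
}

#' Default in silico calibration specification
#'
#' Concentration means set to the literature reference-range midpoints and
#' SDs to a quarter of the range width, except albumin, which is widened
#' (mean 100, SD 120 mg/L, truncated at zero) so the calibration set spans
#' normo- to macroalbuminuria. Urea, creatinine, sulfate and phosphate are
#' correlated via [default_concentration_correlations()] (placeholder
#' values).
#'
#' @param n number of calibration samples, default 100.
#' @param seed sampling seed.
#' @param condition pretreatment condition (default 25x, 0 cleaning steps,
#'   10 scans on the portable instrument).
#' @return list with `means`, `sds`, `corr`, `n`, `seed`, `condition`,
#'   `region`.
#' @export
default_calibration_spec <- function(n = 100, seed = 1,
                                     condition = pretreatment_condition(
                                       preconc_nominal = 25, cleaning_steps = 0,
                                       scans = 10, instrument = "spectrum_two")) {
  tab <- component_table()
  means <- (tab$ref_min + tab$ref_max) / 2
  sds <- (tab$ref_max - tab$ref_min) / 4
  names(means) <- names(sds) <- tab$name
  means[["albumin"]] <- 100
  sds[["albumin"]] <- 120
  list(means = means, sds = sds,
       corr = default_concentration_correlations(tab$name),
       n = n, seed = seed, condition = condition, region = c(950, 1770))
}

#' Simulate a dataset from a sampled-concentration specification
#'
#' Draws the correlated concentration set described by a calibration
#' specification and simulates its spectra under the specification's
#' pretreatment condition. Zero-truncated creatinine draws are floored at
#' the smallest positive draw so every sample has a defined UACR.
#'
#' @param calib_spec a specification (see [default_calibration_spec()]).
#' @param library a `spectral_library`.
#' @param noise_lib a `noise_library`.
#' @param seed master seed (defaults to the specification's own).
#' @return a `sim_dataset`.
#' @export
simulate_from_spec <- function(calib_spec, library = default_component_library(),
                               noise_lib = noise_library(axis = library$axis),
                               seed = calib_spec$seed) {
  cs <- calib_spec
  conc <- sample_concentrations(cs$means, cs$sds, cs$corr, n = cs$n,
                                seed = derive_seed(seed, "sampled_conc"))
  creat <- conc$concentrations[, "creatinine"]
  if (any(creat <= 0)) {
    conc$concentrations[creat <= 0, "creatinine"] <- min(creat[creat > 0])
  }
  suppressWarnings(
    simulate_dataset(conc, cs$condition, library, noise_lib, seed = seed)
  )
}

#' Calibrate a PLS-DA model in silico and predict a target dataset
#'
#' Samples a correlated concentration set, simulates its spectra under the
#' calibration condition, preprocesses (WLSB, SNV, first derivative) and
#' restricts to the classification region, selects the LV count by inner
#' venetian-blinds CV with the incremental rule, fits a PLS-DA for
#' albuminuria (UACR >= 30 mg/g from the sampled albumin/creatinine), and
#' predicts the target dataset. The target spectra are resampled onto the
#' calibration axis when the axes differ.
#'
#' @param calib_spec a calibration specification (see
#'   [default_calibration_spec()]).
#' @param target a `sim_dataset` (or list with `spectra`, `axis` and
#'   `labels$albuminuric`).
#' @param library a `spectral_library`.
#' @param noise_lib a `noise_library`.
#' @param max_lv maximum LVs assessed.
#' @return list with `proba`, `class`, `auroc`, `class_error`, `n_lv`, and
#'   the fitted `model`.
#' @export
insilico_calibrate_and_predict <- function(calib_spec, target,
                                           library = default_component_library(),
                                           noise_lib = noise_library(axis = library$axis),
                                           max_lv = 10) {
  cs <- calib_spec
  ds <- simulate_from_spec(cs, library, noise_lib, seed = cs$seed)
  if (length(unique(ds$labels$albuminuric)) < 2) {
    stop("calibration set contains a single albuminuria class", call. = FALSE)
  }
  pre <- preprocess_spectra(ds$spectra, ds$axis)
  Xc <- select_region(pre, attr(pre, "axis"), cs$region[1], cs$region[2])
  cv <- venetian_cv(Xc, as.numeric(ds$labels$albuminuric), max_lv = max_lv)
  lv <- select_lv_incremental(cv)
  model <- fit_plsda(Xc, ds$labels$albuminuric, lv)
  Xt <- target$spectra
  if (!axes_equal(as_wn_axis(target$axis), ds$axis)) {
    Xt <- t(apply(Xt, 1, function(row) {
      resample(new_spectrum(target$axis, row), ds$axis)$absorbance
    }))
  }
  pret <- preprocess_spectra(Xt, ds$axis)
  Xtr <- select_region(pret, attr(pret, "axis"), cs$region[1], cs$region[2])
  proba <- predict_proba(model, Xtr)
  cls <- classify(model, Xtr)
  res <- list(proba = proba, class = cls, n_lv = lv, model = model)
  if (!is.null(target$labels$albuminuric)) {
    res$auroc <- auroc(proba, target$labels$albuminuric)
    res$class_error <- classification_error(cls, target$labels$albuminuric)
  }
  res
}
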