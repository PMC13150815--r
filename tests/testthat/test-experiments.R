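test_that("the default condition grid covers the full factorial", {
  conds <- grid_conditions()
  expect_length(conds, 4 * 3 * 5)
  key <- vapply(conds, function(cd) {
    paste(cd$preconc_nominal, cd$cleaning_steps, cd$scans, cd$instrument)
  }, character(1))
  expect_identical(anyDuplicated(key), 0L)
  conds2 <- grid_conditions(instruments = c("spectrum_two", "spectrum_3"))
  expect_length(conds2, 120)
  expect_error(run_grid(tiny_design(), tiny_library(), list()), "empty")
})

test_that("run_grid records one deterministic row per condition and analyte", {
  lib <- default_component_library()
  design <- levels_to_concentrations(brereton_design(13), default_ranges())
  nl <- noise_library(axis = lib$axis)
  conds <- grid_conditions(preconc = c(1, 25), cleaning = 0, scans = 10)
  res <- run_grid(design, lib, conds, seed = 1, noise_lib = nl)
  expect_identical(nrow(res), 4L)
  expect_setequal(res$analyte, c("creatinine", "albumin"))
  expect_true(all(res$rmsecv >= 0))
  res2 <- run_grid(design, lib, conds, seed = 1, noise_lib = nl)
  expect_identical(res, res2)
})

test_that("raw urine shows no albumin predictivity at short acquisition", {
  lib <- default_component_library()
  design <- levels_to_concentrations(brereton_design(13), default_ranges())
  nl <- noise_library(axis = lib$axis)
  res <- run_grid(design, lib,
                  grid_conditions(preconc = 1, cleaning = 0, scans = 1),
                  seed = 1, noise_lib = nl)
  expect_lt(res$r2cv[res$analyte == "albumin"], 0.3)
})

test_that("MC2CV produces the requested number of reproducible splits", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- drop(X %*% rnorm(5))  # exactly linear: PLS at full rank is exact
  res <- mc2cv(X, y, n_splits = 20, seed = 3, max_lv = 5, lv_rule = "min")
  expect_length(res$rmsep, 20)
  expect_length(res$splits, 20)
  for (s in res$splits) {
    expect_length(s, round(0.3 * 40))
    expect_length(intersect(s, setdiff(seq_len(40), s)), 0)
  }
  # split sequence depends only on (seed, n): a different dataset of equal
  # size shares the splits
  X2 <- matrix(rnorm(40 * 4), 40, 4)
  res2 <- mc2cv(X2, rnorm(40) + X2[, 1], n_splits = 20, seed = 3, max_lv = 3,
                lv_rule = "min")
  expect_identical(res$splits, res2$splits)
  # noiseless linear data predicts exactly
  expect_lte(max(res$rmsep), 1e-6)
})

test_that("classification MC2CV redraws single-class splits", {
  set.seed(2)
  n <- 30
  lab <- c(rep(TRUE, 4), rep(FALSE, n - 4))  # rare positives force redraws
  X <- cbind(ifelse(lab, 3, -3) + rnorm(n), matrix(rnorm(n * 3), n, 3))
  res <- mc2cv(X, lab, n_splits = 10, seed = 1, max_lv = 2, k = 5)
  expect_length(res$auroc, 10)
  for (s in res$splits) {
    expect_gt(length(unique(lab[s])), 1)
    expect_gt(length(unique(lab[-s])), 1)
  }
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
})

test_that("distribution comparison wraps the standard two-sided tests", {
  set.seed(3)
  a <- rnorm(100)
  b <- a + rnorm(100, 0, 1e-6)  # symmetric jitter around identity
  expect_gt(compare_distributions(a, b, "wilcoxon_ranksum")$p_value, 0.5)
  shifted <- rnorm(100, 3, 1)
  base <- rnorm(100, 0, 1)
  expect_lt(compare_distributions(base, shifted, "welch_t")$p_value, 1e-6)
  expect_lt(compare_distributions(base, shifted, "wilcoxon_ranksum")$p_value, 1e-6)
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
})

test_that("in silico calibration discriminates an independently simulated target", {
  lib <- default_component_library()
  nl <- noise_library(axis = lib$axis)
  spec <- default_calibration_spec(n = 100, seed = 11)
  # an independently simulated labelled dataset from the same generative spec
  target <- simulate_from_spec(spec, lib, nl, seed = 202)
  res <- insilico_calibrate_and_predict(spec, target, lib, nl)
  expect_gte(res$auroc, 0.9)
  expect_length(res$proba, 100)
  expect_true(all(res$proba >= 0 & res$proba <= 1))
})

test_that("single-class calibration sets are rejected", {
  lib <- default_component_library()
  nl <- noise_library(axis = lib$axis)
  spec <- default_calibration_spec(n = 30, seed = 5)
  spec$means[["albumin"]] <- 5000  # everyone albuminuric
  spec$sds[["albumin"]] <- 1
  design <- levels_to_concentrations(brereton_design(13), default_ranges())
  target <- suppressWarnings(simulate_dataset(design, spec$condition, lib, nl,
                                              seed = 7))
  expect_error(
    suppressWarnings(insilico_calibrate_and_predict(spec, target, lib, nl)),
    "single albuminuria class")
})
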