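test_that("the mixture model reduces to its closed-form limits", {
  lib <- tiny_library()
  n <- length(lib$components)
  w <- lib$water$absorbance
  zero <- setNames(rep(0, n), names(lib$components))
  s_all <- setNames(vapply(lib$components, `[[`, numeric(1),
                           "standard_concentration"), names(lib$components))

  blank <- simulate_spectrum(zero, lib, mode = "verbatim")
  expect_equal(blank$absorbance, n * w)

  full <- simulate_spectrum(s_all, lib, mode = "verbatim")
  b_sum <- Reduce(`+`, lapply(lib$components, function(cc) cc$spectrum$absorbance))
  expect_equal(full$absorbance, b_sum)

  one <- zero; one["urea"] <- s_all["urea"] / 2
  lib1 <- lib; lib1$components <- lib$components["urea"]
  half <- simulate_spectrum(one["urea"], lib1)
  expect_equal(half$absorbance,
               0.5 * lib$components$urea$spectrum$absorbance + 0.5 * w)

  # single-water mode keeps exactly one water contribution for a blank
  blank1 <- simulate_spectrum(zero, lib, mode = "single_water")
  expect_equal(blank1$absorbance, w)
})

test_that("extrapolation above the standard warns; unknown components error", {
  lib <- tiny_library()
  conc <- c(urea = 2 * 150000, albumin = 0, NaCl = 0)
  expect_warning(simulate_spectrum(conc, lib), "extrapolating")
  expect_error(simulate_spectrum(c(propanol = 10), lib), "no library entry")
})

test_that("simulation is linear in concentrations (noise off)", {
  lib <- tiny_library()
  conc <- c(urea = 9000, albumin = 150, NaCl = 4000)
  zero <- setNames(rep(0, 3), names(conc))
  for (mode in c("verbatim", "single_water")) {
    s0 <- simulate_spectrum(zero, lib, mode = mode)$absorbance
    s1 <- simulate_spectrum(conc, lib, mode = mode)$absorbance
    s3 <- simulate_spectrum(3 * conc, lib, mode = mode)$absorbance
    expect_equal(s3 - s0, 3 * (s1 - s0), tolerance = 1e-12)
  }
})

test_that("added noise matches the noise model's sigma", {
  # the truncated axis clips the fingerprint bands; only noise matters here
  lib <- suppressWarnings(tiny_library(make_axis(1000, 1100, 2)))
  nm <- parametric_noise_model("spectrum_two", 1, 2e-3, lib$axis)
  conc <- c(urea = 9000, albumin = 150, NaCl = 4000)
  reps <- t(vapply(1:200, function(i) {
    simulate_spectrum(conc, lib, noise_model = nm, seed = i)$absorbance
  }, numeric(length(lib$axis))))
  sds <- apply(reps, 2, sd)
  band <- 2e-3 * sqrt(qchisq(c(5e-5, 1 - 5e-5), df = 199) / 199)
  expect_true(all(sds >= band[1] & sds <= band[2]))
})

test_that("datasets are bit-identical under one seed", {
  lib <- tiny_library()
  design <- tiny_design()
  nl <- noise_library(axis = lib$axis)
  cond <- pretreatment_condition(preconc_nominal = 25, scans = 4)
  d1 <- simulate_dataset(design, cond, lib, nl, seed = 17)
  d2 <- simulate_dataset(design, cond, lib, nl, seed = 17)
  expect_identical(d1$spectra, d2$spectra)
  expect_identical(d1$realized_factors, d2$realized_factors)
})

test_that("conditions sharing instrument and scans share noise realizations", {
  lib <- tiny_library()
  design <- tiny_design()
  nl <- noise_library(axis = lib$axis)
  c0 <- pretreatment_condition(preconc_nominal = 25, cleaning_steps = 0, scans = 10)
  c1 <- pretreatment_condition(preconc_nominal = 25, cleaning_steps = 1, scans = 10)
  d0 <- simulate_dataset(design, c0, lib, nl, seed = 5)
  d1 <- simulate_dataset(design, c1, lib, nl, seed = 5)
  noiseless0 <- simulate_dataset(design, c0, lib, NULL, seed = 5)
  noiseless1 <- simulate_dataset(design, c1, lib, NULL, seed = 5)
  expect_equal(d0$spectra - noiseless0$spectra, d1$spectra - noiseless1$spectra)
  # and all conditions share the preconcentration error quantiles
  expect_identical(d0$realized_factors, d1$realized_factors)
})

test_that("the mean of many noisy replicates converges to the noiseless spectrum", {
  lib <- suppressWarnings(tiny_library(make_axis(1000, 1060, 2)))
  nm <- parametric_noise_model("spectrum_two", 1, 2e-3, lib$axis)
  conc <- c(urea = 9000, albumin = 150, NaCl = 4000)
  clean <- simulate_spectrum(conc, lib)$absorbance
  n <- 1000
  acc <- rowMeans(vapply(1:n, function(i) {
    simulate_spectrum(conc, lib, noise_model = nm, seed = 1000 + i)$absorbance
  }, numeric(length(lib$axis))))
  expect_true(all(abs(acc - clean) <= 3 * 2e-3 / sqrt(n) * 1.5))
})

test_that("UACR and the albuminuria flag follow the 30 mg/g threshold", {
  u <- compute_uacr(30, 1000)
  expect_equal(u$uacr, 30)
  expect_true(u$albuminuric)  # UACR < 30 defines normoalbuminuria
  u0 <- compute_uacr(0, 1000)
  expect_equal(u0$uacr, 0)
  expect_false(u0$albuminuric)
  expect_error(compute_uacr(30, 0), "positive")
})

test_that("dataset labels come from the nominal albumin/creatinine", {
  lib <- default_component_library()
  design <- levels_to_concentrations(brereton_design(13), default_ranges())
  ds <- suppressWarnings(simulate_dataset(
    design, pretreatment_condition(preconc_nominal = 25, scans = 10),
    lib, noise_library(axis = lib$axis), seed = 1))
  expect_identical(nrow(ds$spectra), 49L)
  expect_identical(nrow(ds$labels), 49L)
  expect_equal(ds$labels$uacr,
               design$concentrations[, "albumin"] /
                 (design$concentrations[, "creatinine"] / 1000))
})

test_that("water subtraction recovers known water multiples", {
  lib <- tiny_library()
  w <- lib$water
  zero <- setNames(rep(0, 3), names(lib$components))

  unit <- subtract_water(w, w, mode = "unit")
  expect_equal(unit$absorbance, rep(0, length(w$axis)))

  blank <- simulate_spectrum(zero, lib, mode = "verbatim")
  fitted <- subtract_water(blank, w, mode = "fit",
                           window = range(as.numeric(w$axis)))
  expect_equal(fitted$meta$water_scale, 3, tolerance = 1e-9)
  expect_equal(max(abs(fitted$absorbance)), 0, tolerance = 1e-9)

  spiked <- new_spectrum(w$axis, 0.3 * w$absorbance)
  k <- subtract_water(spiked, w, mode = "fit",
                      window = range(as.numeric(w$axis)))$meta$water_scale
  expect_equal(k, 0.3, tolerance = 1e-6)

  expect_error(subtract_water(w, w, mode = "fit", window = c(5000, 6000)),
               "empty")
})
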