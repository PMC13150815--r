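# Shared fixtures: a small fingerprint-only axis and a three-component
# library keep per-test simulation cheap.

small_axis <- function() make_axis(900, 1800, 2)

tiny_library <- function(axis = small_axis()) {
  water <- water_spectrum(axis)
  comps <- list(
    synth_component("urea", list(band_model(1626, 22, 0.5),
                                 band_model(1599, 20, 0.45),
                                 band_model(1466, 40, 0.35)),
                    s = 150000, axis, water, mol_class = "low_mw"),
    synth_component("albumin", list(band_model(1652, 60, 0.11),
                                    band_model(1548, 55, 0.075)),
                    s = 15000, axis, water, mol_class = "protein"),
    synth_component("NaCl", list(), s = 52000, axis, water,
                    mol_class = "non_absorbing_salt"))
  names(comps) <- vapply(comps, `[[`, character(1), "name")
  structure(list(components = comps, water = water, axis = as_wn_axis(axis)),
            class = "spectral_library")
}

tiny_design <- function(n = 12, seed = 99) {
  set.seed(seed)
  conc <- cbind(urea = runif(n, 5000, 28000),
                albumin = runif(n, 0, 300),
                NaCl = runif(n, 1000, 10000))
  uirsim:::new_conc_design(conc, provenance = "sampled")
}

identity_condition <- function(scans = 10, instrument = "spectrum_two") {
  pretreatment_condition(preconc_nominal = 1, preconc_cv = 0,
                         cleaning_steps = 0, scans = scans,
                         instrument = instrument)
}
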