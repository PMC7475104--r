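# memoised component bundles shared across test files (preparing the
# spectra involves a few hundred kernel convolutions; do it once)
.component_cache <- new.env(parent = emptyenv())

test_components <- function(x_cm = 20, ...) {
  key <- sprintf("x%.3f_%s", x_cm, paste(deparse(substitute(list(...))),
                                         collapse = ""))
  if (is.null(.component_cache[[key]])) {
    .component_cache[[key]] <- prepare_components(x_cm, ...)
  }
  .component_cache[[key]]
}

# single-line nuclide tibble in the shape emission_lines() returns
fake_lines <- function(energy_kev, intensity, label = "Th227") {
  tibble::tibble(nuclide = label, energy_kev = energy_kev,
                 intensity = intensity, label = label)
}

# small quiet phantom: one disc compartment on an 8x8-compatible grid
tiny_phantom <- function(a_th0 = 0.5, a_ra0 = 0.1, x_cm = 20,
                         room_cps = rep(0, 4)) {
  phantom_spec(tibble::tibble(
    label = "disc", shape = "disc", center_row = 7.5, center_col = 7.5,
    size_px = 3, a_th0 = a_th0, a_ra0 = a_ra0),
    x_cm = x_cm, room_background_cps = room_cps)
}

tiny_plan <- function(times_d = 0, seed = 1, matrix_dim = 16,
                      blur_fwhm_mm = 0, ...) {
  acquisition_plan(times_d = times_d, seed = seed, matrix_dim = matrix_dim,
                   blur_fwhm_mm = blur_fwhm_mm, ...)
}
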