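# Bundled attenuation tables and log-log interpolation.

read_coefficient_table <- function(path, value_col) {
  tab <- as_tibble(read.delim(path, comment.char = "#"))
  stopifnot(all(c("energy_kev", value_col) %in% names(tab)))
  if (any(diff(tab$energy_kev) <= 0)) abort("table energies must be ascending")
  if (any(tab[[value_col]] <= 0)) abort("table coefficients must be positive")
  tab
}

#' Water attenuation coefficient table
#'
#' Narrow-beam total linear attenuation coefficient of water *without*
#' coherent scattering, per cm, tabulated over 15-800 keV. Bundled
#' representative values from standard mass-attenuation compilations
#' (density 1 g/cm3); replaceable via `path`.
#'
#' @param path Optional path to a replacement two-column table
#'   (`energy_kev`, `mu_per_cm`, `#` comments allowed).
#' @return A tibble with `energy_kev` and `mu_per_cm`.
#' @export
attenuation_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mu_water.tsv", package = "thoraquant")
  read_coefficient_table(path, "mu_per_cm")
}

#' NaI(Tl) photoelectric coefficient table
#'
#' Photoelectric linear attenuation coefficient of NaI, per cm, including the
#' iodine K-edge at 33.17 keV. Bundled representative values; replaceable via
#' `path`.
#'
#' @param path Optional path to a replacement two-column table
#'   (`energy_kev`, `tau_per_cm`).
#' @return A tibble with `energy_kev` and `tau_per_cm`.
#' @export
nai_photoelectric_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tau_nai.tsv", package = "thoraquant")
  read_coefficient_table(path, "tau_per_cm")
}

#' Log-log interpolation of a coefficient table
#'
#' Attenuation coefficients are close to power laws in energy between
#' absorption edges, so interpolation is linear in log(coefficient) vs
#' log(energy). Queries outside the tabulated range are rejected.
#'
#' @param table A tibble from [attenuation_table()] or
#'   [nai_photoelectric_table()].
#' @param energy_kev Query energies (keV).
#' @return Interpolated coefficients (per cm).
#' @export
interp_coefficient <- function(table, energy_kev) {
  value_col <- setdiff(names(table), "energy_kev")[1]
  rng <- range(table$energy_kev)
  if (any(energy_kev < rng[1] | energy_kev > rng[2])) {
    abort(sprintf("energy outside tabulated range [%g, %g] keV", rng[1], rng[2]))
  }
  exp(approx(log(table$energy_kev), log(table[[value_col]]),
             xout = log(energy_kev), ties = "ordered")$y)
}
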