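#' Prepare component spectra and window integrals for a given thickness
#'
#' Bundles everything the unmixing fit needs at one water-equivalent
#' thickness: the primary window integrals per unit activity for each
#' isotope group (counts/s/MBq), the unit-normalised scatter-shape window
#' fractions, and the per-window scatter coefficients nu.
#'
#' @param x_cm Water-equivalent thickness (cm) for the geometric-mean
#'   attenuation.
#' @param windows Acquisition windows, see [default_windows()].
#' @param coll,det Collimator and detector specs, see [collimator_spec()].
#' @param att,tau Physics tables.
#' @param scatter_basis Either `"parametric"` (bundled single-scatter model
#'   at this thickness) or a list with elements `th` and `ra`, each a
#'   `scatter_spectrum` (e.g. from [load_scatter_basis()]). External bases
#'   are renormalised to unit integral over the grid.
#' @param nu Scatter coefficient tibble, see
#'   [default_scatter_coefficients()] and [calibrate_nu()]. If the
#'   coefficients were calibrated at a different reference thickness a
#'   warning is emitted (they still apply globally).
#' @param low_cutoff_kev Emission lines below this energy are excluded from
#'   forward modelling.
#' @return A list of class `"window_components"` with elements `x_cm`,
#'   `windows`, `p_th`, `p_ra` (primary window rates, counts/s/MBq),
#'   `s_th`, `s_ra` (scatter window fractions), `nu_th`, `nu_ra`, `spectra`
#'   (the four full component spectra) and `physics` (inputs, for reuse).
#' @export
prepare_components <- function(x_cm,
                               windows = default_windows(),
                               coll = collimator_spec(),
                               det = detector_spec(),
                               att = attenuation_table(),
                               tau = nai_photoelectric_table(),
                               scatter_basis = "parametric",
                               nu = default_scatter_coefficients(),
                               low_cutoff_kev = 20) {
  lines_th <- emission_lines("Th227")
  lines_ra <- emission_lines("Ra223chain")
  p_th_spec <- primary_spectrum(lines_th, x_cm, coll, det, att, tau,
                                low_cutoff_kev = low_cutoff_kev)
  p_ra_spec <- primary_spectrum(lines_ra, x_cm, coll, det, att, tau,
                                low_cutoff_kev = low_cutoff_kev)
  if (identical(scatter_basis, "parametric")) {
    s_th_spec <- parametric_scatter(lines_th, x_cm, det, att, low_cutoff_kev)
    s_ra_spec <- parametric_scatter(lines_ra, x_cm, det, att, low_cutoff_kev)
  } else {
    stopifnot(is.list(scatter_basis), all(c("th", "ra") %in% names(scatter_basis)))
    normalise <- function(s) {
      tot <- sum(s$value)
      if (tot <= 0) abort("scatter basis integrates to zero")
      s$value <- s$value / tot
      s
    }
    s_th_spec <- normalise(scatter_basis$th)
    s_ra_spec <- normalise(scatter_basis$ra)
  }
  ref <- unique(stats::na.omit(nu$reference_thickness_cm))
  if (length(ref) == 1 && abs(ref - x_cm) > 1) {
    warn(sprintf(paste0("scatter coefficients were calibrated at %.1f cm but ",
                        "are applied at %.1f cm"), ref, x_cm))
  }
  structure(list(
    x_cm = x_cm,
    windows = windows,
    p_th = window_integral(p_th_spec, windows),
    p_ra = window_integral(p_ra_spec, windows),
    s_th = window_integral(s_th_spec, windows),
    s_ra = window_integral(s_ra_spec, windows),
    nu_th = nu_vector(nu, "Th227", windows),
    nu_ra = nu_vector(nu, "Ra223", windows),
    spectra = list(p_th = p_th_spec, p_ra = p_ra_spec,
                   s_th = s_th_spec, s_ra = s_ra_spec),
    physics = list(coll = coll, det = det, att = att, tau = tau,
                   lines_th = lines_th, lines_ra = lines_ra,
                   low_cutoff_kev = low_cutoff_kev,
                   scatter_basis = scatter_basis)
  ), class = "window_components")
}

#' @export
print.window_components <- function(x, ...) {
  cat("<window_components> at x =", x$x_cm, "cm\n")
  print(tibble(window = x$windows$window,
               p_th227_cps_mbq = unname(x$p_th),
               p_ra223_cps_mbq = unname(x$p_ra),
               s_th227_frac = unname(x$s_th),
               s_ra223_frac = unname(x$s_ra),
               nu_th227 = x$nu_th, nu_ra223 = x$nu_ra))
  invisible(x)
}

#' Update the scatter coefficients of a component bundle
#'
#' @param components A [prepare_components()] bundle.
#' @param nu A scatter-coefficient tibble.
#' @return The bundle with `nu_th` / `nu_ra` replaced.
#' @export
set_scatter_coefficients <- function(components, nu) {
  components$nu_th <- nu_vector(nu, "Th227", components$windows)
  components$nu_ra <- nu_vector(nu, "Ra223", components$windows)
  components
}
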