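new_scatter_spectrum <- function(grid, values, isotope, provenance,
                                 reference_thickness_cm = NA_real_) {
  out <- structure(tibble(energy_kev = grid, value = values, isotope = isotope),
                   class = c("scatter_spectrum", "tbl_df", "tbl", "data.frame"))
  attr(out, "provenance") <- provenance
  attr(out, "reference_thickness_cm") <- reference_thickness_cm
  out
}

#' Load an externally tabulated scatter basis spectrum
#'
#' Reads a two-column (energy_keV, relative counts) table — e.g. a Monte
#' Carlo scatter spectrum — and resamples it onto the standard 1-keV grid by
#' linear interpolation; energies outside the tabulated range map to 0. The
#' absolute scale of a scatter basis is irrelevant (it is absorbed by the
#' fitted scale B), only the shape matters.
#'
#' @param table A data frame with columns `energy_kev` and `value`, or a path
#'   to a delimited text file with those columns (`#` comments allowed).
#' @param isotope `"Th227"` or `"Ra223"`.
#' @param reference_thickness_cm Water thickness the spectrum was generated
#'   for (metadata).
#' @return A `scatter_spectrum` tibble on the standard grid.
#' @export
load_scatter_basis <- function(table, isotope = c("Th227", "Ra223"),
                               reference_thickness_cm = NA_real_) {
  isotope <- match.arg(isotope)
  if (is.character(table)) table <- read.delim(table, comment.char = "#")
  stopifnot(all(c("energy_kev", "value") %in% names(table)))
  if (any(diff(table$energy_kev) <= 0)) abort("energies must be ascending")
  if (any(table$value < 0)) abort("scatter basis values must be non-negative")
  grid <- energy_grid()
  v <- approx(table$energy_kev, table$value, xout = grid,
              yleft = 0, yright = 0, rule = 1)$y
  v[is.na(v)] <- 0
  new_scatter_spectrum(grid, v, isotope, "external", reference_thickness_cm)
}

# Klein-Nishina single-scatter continuum of one line, on the standard grid.
# Returns unnormalised bin weights of the scattered-photon energy E'.
kn_continuum <- function(e0, n_angles = 2000) {
  grid <- energy_grid()
  cth <- seq(-1, 1, length.out = n_angles)
  alpha <- e0 / 511
  ep <- e0 / (1 + alpha * (1 - cth))
  ratio <- ep / e0
  w <- ratio^2 * (ratio + 1 / ratio - (1 - cth^2))   # dsigma/dcos(theta)
  idx <- findInterval(ep, c(grid - 0.5, grid[length(grid)] + 0.5))
  ok <- idx >= 1 & idx <= length(grid)
  v <- numeric(length(grid))
  tab <- tapply(w[ok], idx[ok], sum)
  v[as.integer(names(tab))] <- tab
  v
}

# Energy-dependent resolution blur of a whole spectrum (column j of the
# kernel is the spread of a unit mass at grid energy E_j).
blur_spectrum <- function(values, det) {
  grid <- energy_grid()
  out <- numeric(length(grid))
  nz <- which(values > 0)
  for (j in nz) {
    out <- out + spread_line(grid, grid[j], values[j],
                             energy_resolution(det, grid[j]))
  }
  out
}

#' Parametric single-scatter basis spectrum
#'
#' A bundled stand-in for Monte Carlo scatter spectra: each emission line of
#' energy E0 contributes a single-Compton-scatter continuum from the
#' backscatter limit E0/(1 + 2 E0/511) up to E0, shaped by the Klein-Nishina
#' energy distribution, weighted by the line intensity and a
#' thickness-dependent scatter fraction \eqn{1 - e^{-\mu(E_0) x / 2}}, then
#' blurred with the detector energy resolution. The result is normalised to
#' unit integral: per the model's separation of scatter shape and scale,
#' absolute scale lives entirely in the fitted coefficient B (and the
#' per-window coefficients nu).
#'
#' @param lines Emission lines from [emission_lines()].
#' @param x_cm Water thickness generating the scatter (> 0).
#' @param det Detector spec (for the resolution blur).
#' @param att Water attenuation table.
#' @param low_cutoff_kev Lines below this energy are ignored.
#' @return A unit-integral `scatter_spectrum` on the standard grid.
#' @export
parametric_scatter <- function(lines, x_cm, det = detector_spec(),
                               att = attenuation_table(),
                               low_cutoff_kev = 20) {
  if (x_cm <= 0) abort("x_cm must be positive")
  grid <- energy_grid()
  keep <- lines$energy_kev >= low_cutoff_kev &
    lines$energy_kev <= max(grid) + 0.5
  lines <- lines[keep, , drop = FALSE]
  values <- numeric(length(grid))
  for (i in seq_len(nrow(lines))) {
    e0 <- lines$energy_kev[i]
    frac <- 1 - exp(-interp_coefficient(att, e0) * x_cm / 2)
    cont <- kn_continuum(e0)
    if (sum(cont) > 0) {
      values <- values + lines$intensity[i] * frac * cont / sum(cont)
    }
  }
  values <- blur_spectrum(values, det)
  values <- values / sum(values)
  iso <- if (startsWith(lines$label[1] %||% "Th227", "Th")) "Th227" else "Ra223"
  new_scatter_spectrum(grid, values, iso, "parametric", x_cm)
}

#' Per-window scatter scaling coefficients
#'
#' The empirical coefficients nu adapt the fixed scatter-basis shape to a
#' measured geometry: one multiplier per isotope per acquisition window
#' (8 values). `default_scatter_coefficients()` returns the identity set
#' (all 1).
#'
#' @param windows Window tibble, see [default_windows()].
#' @param reference_thickness_cm Thickness the coefficients were calibrated
#'   at (metadata; `NA` for the identity default).
#' @return A tibble with columns `isotope`, `window`, `nu`,
#'   `reference_thickness_cm`.
#' @export
default_scatter_coefficients <- function(windows = default_windows(),
                                         reference_thickness_cm = NA_real_) {
  tidyr::expand_grid(isotope = c("Th227", "Ra223"), window = windows$window) |>
    dplyr::mutate(nu = 1, reference_thickness_cm = reference_thickness_cm)
}

nu_vector <- function(nu, isotope, windows = default_windows()) {
  sub <- nu[nu$isotope == isotope, , drop = FALSE]
  out <- sub$nu[match(windows$window, sub$window)]
  if (anyNA(out)) abort(sprintf("missing nu entries for isotope %s", isotope))
  out
}

#' Scatter window integrals with nu scaling
#'
#' For each acquisition window j, returns
#' \eqn{\nu_{iso,j} \int_j S(E)\, dE}.
#'
#' @param s A `scatter_spectrum`.
#' @param nu A scatter-coefficient tibble, see
#'   [default_scatter_coefficients()].
#' @param windows Window tibble.
#' @return Named numeric vector, one value per window.
#' @export
scatter_window_integrals <- function(s, nu = default_scatter_coefficients(),
                                     windows = default_windows()) {
  iso <- s$isotope[1]
  window_integral(s, windows) * nu_vector(nu, iso, windows)
}

#' Calibrate the scatter scaling coefficients
#'
#' Determines the per-window coefficients nu empirically from measurements
#' with *known* activities, mirroring the two-stage phantom procedure:
#' Th-227 coefficients from an early (Th-dominant, minimal Ra ingrowth)
#' measurement, then Ra-223 coefficients from a late measurement holding the
#' Th coefficients fixed. Because the early data still contain a small Ra
#' term, the two stages are iterated to convergence. With 4 windows and 4
#' coefficients per isotope the system is exactly determined: re-applying
#' the calibrated coefficients reproduces the calibration counts.
#'
#' B and nu enter the model only as a product, so calibration is performed
#' at the fixed scale `b` (default 1); fitted B values are then relative to
#' that convention.
#'
#' @param th_meas,ra_meas Lists with elements `gm_counts` (numeric(4),
#'   background-corrected geometric-mean counts per window), `duration_s`,
#'   and known activities `a_th` and `a_ra` (MBq) at acquisition time.
#' @param components A [prepare_components()] bundle (its nu entries are
#'   ignored; its primary and scatter window integrals are used).
#' @param b Scatter scale convention used during calibration.
#' @param max_iter,tol Iteration controls for the two-stage alternation.
#' @return A scatter-coefficient tibble (8 rows).
#' @export
calibrate_nu <- function(th_meas, ra_meas, components, b = 1,
                         max_iter = 100, tol = 1e-12) {
  cmp <- components
  solve_stage <- function(meas, s_own, p_own, a_own, other_term) {
    # per window: meas/d = aT pT + aR pR + b(a_own nu_own s_own + other_term)
    num <- meas$gm_counts / meas$duration_s -
      meas$a_th * cmp$p_th - meas$a_ra * cmp$p_ra - b * other_term
    den <- b * a_own * s_own
    nu <- rep(1, length(num))
    ok <- den > .Machine$double.eps
    nu[ok] <- num[ok] / den[ok]
    if (any(!ok)) {
      warn("zero scatter integral (or zero activity) in a window; nu set to 1")
    }
    if (any(nu[ok] <= 0)) {
      warn("non-positive nu from calibration data; clamped to 1e-6")
      nu[ok] <- pmax(nu[ok], 1e-6)
    }
    nu
  }
  nu_th <- rep(1, 4)
  nu_ra <- rep(1, 4)
  for (it in seq_len(max_iter)) {
    nu_th_new <- solve_stage(th_meas, cmp$s_th, cmp$p_th, th_meas$a_th,
                             th_meas$a_ra * nu_ra * cmp$s_ra)
    nu_ra_new <- solve_stage(ra_meas, cmp$s_ra, cmp$p_ra, ra_meas$a_ra,
                             ra_meas$a_th * nu_th_new * cmp$s_th)
    delta <- max(abs(nu_th_new - nu_th), abs(nu_ra_new - nu_ra))
    nu_th <- nu_th_new
    nu_ra <- nu_ra_new
    if (delta < tol) break
  }
  windows <- cmp$windows
  dplyr::bind_rows(
    tibble(isotope = "Th227", window = windows$window, nu = nu_th,
           reference_thickness_cm = cmp$x_cm),
    tibble(isotope = "Ra223", window = windows$window, nu = nu_ra,
           reference_thickness_cm = cmp$x_cm))
}
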