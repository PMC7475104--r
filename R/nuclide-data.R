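#' Photon emission lines of the Th-227 decay chain
#'
#' Returns the bundled gamma/x-ray emission lines (abundance > 1%) for either
#' `"Th227"` alone or `"Ra223chain"`, which aggregates Ra-223 and its
#' short-lived daughters (Rn-219, Pb-211, Bi-211, Tl-207). The daughters have
#' half-lives of seconds to minutes, so on imaging timescales (hours to days
#' after filling) they are in secular equilibrium with Ra-223 and their lines
#' are folded in at their tabulated intensities with unit branching.
#'
#' The bundled table derives from the Brookhaven NNDC compilation; an
#' alternative table with the same columns (`nuclide`, `energy_kev`,
#' `intensity`) can be supplied via `path` to accommodate revised intensity
#' data.
#'
#' @param label `"Th227"` or `"Ra223chain"`.
#' @param path Optional path to a replacement tab-delimited line table
#'   (`#` comments allowed).
#' @return A tibble with columns `nuclide`, `energy_kev` (keV) and
#'   `intensity` (photons per decay, fraction in (0, 1]).
#' @examples
#' emission_lines("Th227")
#' @export
emission_lines <- function(label = c("Th227", "Ra223chain"), path = NULL) {
  label <- match.arg(label)
  path <- path %||% system.file("extdata", "emission_lines.tsv",
                                package = "thoraquant")
  tab <- as_tibble(read.delim(path, comment.char = "#"))
  stopifnot(all(c("nuclide", "energy_kev", "intensity") %in% names(tab)))
  if (any(tab$energy_kev <= 0) || any(tab$intensity <= 0 | tab$intensity > 1)) {
    abort("emission line table must have energy_kev > 0 and intensity in (0, 1]")
  }
  members <- switch(label,
    Th227      = "Th227",
    Ra223chain = c("Ra223", "Rn219", "Pb211", "Bi211", "Tl207"))
  out <- dplyr::filter(tab, .data$nuclide %in% members)
  out$label <- label
  dplyr::arrange(out, .data$energy_kev)
}

#' Decay parameters of Th-227 and Ra-223
#'
#' Half-lives of 18.7 d (Th-227) and 11.4 d (Ra-223) and the derived decay
#' constants \eqn{\lambda = \ln 2 / T_{1/2}} in units of per day.
#'
#' @param half_life_th227,half_life_ra223 Half-lives in days; defaults are
#'   the standard compilation values.
#' @return A list with elements `half_life_th227`, `half_life_ra223`,
#'   `lambda_th`, `lambda_ra` (per day).
#' @export
decay_parameters <- function(half_life_th227 = 18.7, half_life_ra223 = 11.4) {
  stopifnot(half_life_th227 > 0, half_life_ra223 > 0)
  p <- list(
    half_life_th227 = half_life_th227,
    half_life_ra223 = half_life_ra223,
    lambda_th = log(2) / half_life_th227,
    lambda_ra = log(2) / half_life_ra223)
  if (p$lambda_ra <= p$lambda_th) {
    abort("expected lambda_ra > lambda_th (daughter shorter-lived than parent)")
  }
  p
}
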