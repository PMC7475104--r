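#' Bateman activity evolution of a Th-227 / Ra-223 fill
#'
#' Propagates the activities of a two-member chain from the fill time
#' ("day 0") to later times using the closed-form Bateman solutions:
#' \deqn{A_{Th}(t) = A_{Th,0}\, e^{-\lambda_{Th} t}}
#' \deqn{A_{Ra}(t) = A_{Th,0}\,\frac{\lambda_{Ra}}{\lambda_{Ra}-\lambda_{Th}}
#'   \left(e^{-\lambda_{Th} t} - e^{-\lambda_{Ra} t}\right)
#'   + A_{Ra,0}\, e^{-\lambda_{Ra} t}}
#' Any interval between purification and filling is the caller's
#' responsibility via the initial activities.
#'
#' @param a_th0,a_ra0 Initial activities (MBq) at time zero; must be >= 0.
#' @param t Times in days since the reference (vectorised); must be >= 0.
#' @param params Decay constants, see [decay_parameters()].
#' @return A tibble with columns `time_d`, `a_th227`, `a_ra223` (MBq).
#' @examples
#' bateman_activities(0.54, 0.014, t = c(0, 2, 29))
#' @export
bateman_activities <- function(a_th0, a_ra0, t, params = decay_parameters()) {
  if (any(t < 0)) abort("t must be non-negative (days since reference)")
  if (a_th0 < 0 || a_ra0 < 0) abort("initial activities must be non-negative")
  lt <- params$lambda_th
  lr <- params$lambda_ra
  a_th <- a_th0 * exp(-lt * t)
  a_ra <- a_th0 * lr / (lr - lt) * (exp(-lt * t) - exp(-lr * t)) +
    a_ra0 * exp(-lr * t)
  tibble(time_d = t, a_th227 = a_th, a_ra223 = a_ra)
}

#' Cumulated activity by trapezoid integration
#'
#' Integrates a sampled time-activity curve with the trapezoid rule. No
#' extrapolation is performed beyond the first or last sample.
#'
#' @param times Sample times (days), strictly increasing, length >= 2.
#' @param activities Activities (MBq) at `times`.
#' @return Cumulated activity in MBq·days.
#' @examples
#' cumulated_activity(c(0, 1), c(1, 1))
#' @export
cumulated_activity <- function(times, activities) {
  if (length(times) != length(activities)) {
    abort("times and activities must have the same length")
  }
  if (length(times) < 2) abort("need at least two samples")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  sum(diff(times) * (utils::head(activities, -1) + utils::tail(activities, -1)) / 2)
}
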