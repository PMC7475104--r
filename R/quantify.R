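#' Quantify a conjugate-view acquisition through ROIs
#'
#' The measurement chain for one time point: subtract the scaled
#' room-background image from each view/window, extract background-corrected
#' ROI counts (main minus paired background ROI) per view, take the
#' conjugate geometric mean per window, and fit the activities by
#' [solve_activities()].
#'
#' @param acq A list with `ant` and `post` lists of 4 [planar_image()]s (as
#'   produced by [simulate_acquisition()], or assembled from
#'   [read_planar()]).
#' @param background `NULL`, or a list with `ant`/`post` room-background
#'   image lists to subtract.
#' @param rois Named list of [roi_circle()]/[roi_rect()]s; one estimate is
#'   produced per ROI.
#' @param components A [prepare_components()] bundle at the acquisition's
#'   water-equivalent thickness.
#' @param weights Passed to [solve_activities()].
#' @return A tibble with one row per ROI: `label`, `a_th227`, `a_ra223`,
#'   `b`, `residual`, `converged`.
#' @export
quantify_acquisition <- function(acq, background = NULL, rois, components,
                                 weights = NULL) {
  nwin <- nrow(components$windows)
  correct <- function(imgs, bkgs) {
    if (is.null(bkgs)) return(imgs)
    purrr::map2(imgs, bkgs, subtract_room_background, quiet = TRUE)
  }
  ant <- correct(acq$ant, background$ant)
  post <- correct(acq$post, background$post)
  purrr::imap_dfr(rois, function(roi, label) {
    gm <- vapply(seq_len(nwin), function(j) {
      conjugate_geometric_mean(roi_counts(ant[[j]], roi),
                               roi_counts(post[[j]], roi))
    }, numeric(1))
    est <- solve_activities(gm, ant[[1]]$duration_s, components,
                            weights = weights)
    tibble(label = label, a_th227 = est$a_th227, a_ra223 = est$a_ra223,
           b = est$b, residual = est$residual, converged = est$converged)
  })
}

#' Quantify every time point of a phantom study
#'
#' Applies [quantify_acquisition()] at each acquisition time of a
#' [simulate_timeseries_study()] result (or any object with the same
#' shape) and joins the ground truth where available.
#'
#' @param study A `phantom_study`.
#' @param rois Named list of ROIs (e.g. [jaszczak_rois()]).
#' @param components A [prepare_components()] bundle.
#' @param weights Passed to [solve_activities()].
#' @return A tibble of class `"study_estimates"`: `time_d`, `label`,
#'   estimated `a_th227`/`a_ra223`, `b`, `residual`, `converged`, and truth
#'   columns `true_a_th227`/`true_a_ra223` when present.
#' @export
quantify_study <- function(study, rois, components, weights = NULL) {
  est <- purrr::imap_dfr(study$acquisitions, function(acq, nm) {
    dplyr::mutate(
      quantify_acquisition(acq, study$background, rois, components, weights),
      time_d = acq$truth$time_d[1], .before = 1)
  })
  if (!is.null(study$truth)) {
    est <- dplyr::left_join(
      est,
      dplyr::rename(study$truth, true_a_th227 = "a_th227",
                    true_a_ra223 = "a_ra223"),
      by = c("time_d", "label"))
  }
  class(est) <- c("study_estimates", class(est))
  est
}

#' Cumulated-activity accuracy of a quantified study
#'
#' Trapezoid-integrates the estimated and true time-activity curves per ROI
#' and isotope and reports the percent difference of the integrals,
#' \eqn{100 (\tilde{A}_{est} - \tilde{A}_{true}) / \tilde{A}_{true}}.
#'
#' @param estimates A [quantify_study()] result containing truth columns.
#' @return A tibble: `label`, `isotope`, `cumulated_est`, `cumulated_true`
#'   (MBq·days), `pct_diff`.
#' @export
study_accuracy <- function(estimates) {
  stopifnot(all(c("true_a_th227", "true_a_ra223") %in% names(estimates)))
  long <- dplyr::bind_rows(
    dplyr::transmute(estimates, .data$label, .data$time_d, isotope = "Th227",
                     est = .data$a_th227, true = .data$true_a_th227),
    dplyr::transmute(estimates, .data$label, .data$time_d, isotope = "Ra223",
                     est = .data$a_ra223, true = .data$true_a_ra223))
  long |>
    dplyr::group_by(.data$label, .data$isotope) |>
    dplyr::arrange(.data$time_d, .by_group = TRUE) |>
    dplyr::summarise(
      cumulated_est = cumulated_activity(.data$time_d, .data$est),
      cumulated_true = cumulated_activity(.data$time_d, .data$true),
      .groups = "drop") |>
    dplyr::mutate(pct_diff = dplyr::if_else(
      .data$cumulated_true > 0,
      100 * (.data$cumulated_est - .data$cumulated_true) / .data$cumulated_true,
      NA_real_))
}
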