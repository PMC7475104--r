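#' Phantom specification for the synthetic simulator
#'
#' Describes a set of active compartments projected into the image plane
#' (discs for spheres/cylinders, rectangles for slabs), the total
#' water-equivalent thickness, and the room-background count rates. Pixel
#' coordinates are 0-based (row, col). `depth_frac` is the anterior depth of
#' the compartment center as a fraction of `x_cm` (0.5 = midline); it
#' controls how the conjugate attenuation splits between the views.
#'
#' @param compartments A tibble with columns `label`, `shape` (`"disc"` or
#'   `"rect"`), `center_row`, `center_col`, `size_px` (disc radius, or
#'   half-width of a square rect), `a_th0`, `a_ra0` (MBq at fill), and
#'   optionally `depth_frac`.
#' @param x_cm Total water-equivalent thickness (cm).
#' @param room_background_cps Room-background count rate per window
#'   (counts/s over the whole field of view), length 4.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(compartments, x_cm = 20,
                         room_background_cps = rep(2, 4)) {
  needed <- c("label", "shape", "center_row", "center_col", "size_px",
              "a_th0", "a_ra0")
  stopifnot(all(needed %in% names(compartments)))
  if (any(compartments$a_th0 < 0) || any(compartments$a_ra0 < 0)) {
    abort("fill activities must be non-negative")
  }
  if (!"depth_frac" %in% names(compartments)) compartments$depth_frac <- 0.5
  structure(list(compartments = as_tibble(compartments), x_cm = x_cm,
                 room_background_cps = room_background_cps),
            class = "phantom_spec")
}

#' Bundled phantom presets
#'
#' `jaszczak_phantom()` mirrors the torso-representative Jaszczak setup:
#' an 83 mL sphere filled with 0.54 MBq Th-227 plus 0.014 MBq Ra-223, a
#' 14.6 mL sphere with 0.15 MBq Ra-223 only, and a warm background
#' compartment with 0.98 MBq Th-227 plus 0.025 MBq Ra-223 (about 40:1
#' sphere-to-background activity concentration in 3-D), behind 20 cm of
#' water. `flat_sensitivity_phantom()` is a 100 x 100 x 5 mm slab filled
#' with 1.33 MBq Th-227 and 0.92 MBq Ra-223.
#'
#' Geometry is projected onto a 64 x 64 matrix with 9.59 mm pixels: sphere
#' radii of 2.71 cm (83 mL) and 1.52 cm (14.6 mL) become 2.83 and 1.58 px.
#' The background compartment projects as a 14 px disc; the controlled
#' quantity is the fill set and concentration ratio, not the compartment
#' volume.
#'
#' @return A [phantom_spec()].
#' @export
jaszczak_phantom <- function() {
  phantom_spec(tibble(
    label      = c("sphere83", "sphere14", "background"),
    shape      = "disc",
    center_row = c(29, 29, 31.5),
    center_col = c(27, 38, 31.5),
    size_px    = c(2.83, 1.58, 14),
    a_th0      = c(0.54, 0, 0.98),
    a_ra0      = c(0.014, 0.15, 0.025)))
}

#' @rdname jaszczak_phantom
#' @export
flat_sensitivity_phantom <- function() {
  phantom_spec(tibble(
    label = "slab", shape = "rect", center_row = 31.5, center_col = 31.5,
    size_px = 5.2, a_th0 = 1.33, a_ra0 = 0.92),
    x_cm = 0.5)
}

#' Oversized sphere ROIs for the Jaszczak preset
#'
#' Circular ROIs larger than the projected spheres (to capture partial
#' volume spill-out), each paired with an identically sized background ROI
#' offset inferiorly, fully inside the warm background compartment.
#'
#' @return Named list of [roi_circle()]s (`sphere83`, `sphere14`).
#' @export
jaszczak_rois <- function() {
  list(sphere83 = roi_circle(c(29, 27), 4.8, c(10, 0)),
       sphere14 = roi_circle(c(29, 38), 3.6, c(10, 0)))
}

#' Acquisition plan for the synthetic simulator
#'
#' @param times_d Imaging times in days since fill; the default is the
#'   13-point schedule day 0 through day 29.
#' @param duration_s Planar acquisition duration (s), default 1200 (20 min).
#' @param seed Master seed; every image drawn by the simulator derives its
#'   own stream from (seed, time index, window index, view index) so any
#'   single image is reproducible in isolation.
#' @param matrix_dim Image matrix size (default 64).
#' @param pixel_size_mm Pixel size (default 9.59 mm).
#' @param blur_fwhm_mm Spatial Gaussian blur FWHM emulating system
#'   resolution / partial-volume spill (default 15 mm; 0 disables).
#' @param background_duration_s Duration of the room-background acquisition
#'   (default 9 h).
#' @param windows Acquisition windows.
#' @return A list of class `"acquisition_plan"`.
#' @export
acquisition_plan <- function(times_d = c(0, 1, 2, 3, 4, 7, 9, 11, 14, 16,
                                         22, 24, 29),
                             duration_s = 1200, seed = 1, matrix_dim = 64,
                             pixel_size_mm = 9.59, blur_fwhm_mm = 15,
                             background_duration_s = 9 * 3600,
                             windows = default_windows()) {
  stopifnot(duration_s > 0, all(times_d >= 0))
  structure(list(times_d = times_d, duration_s = duration_s, seed = seed,
                 matrix_dim = matrix_dim, pixel_size_mm = pixel_size_mm,
                 blur_fwhm_mm = blur_fwhm_mm,
                 background_duration_s = background_duration_s,
                 windows = windows),
            class = "acquisition_plan")
}

compartment_mask <- function(comp, dim) {
  rows <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  cols <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  if (comp$shape == "disc") {
    (rows - comp$center_row)^2 + (cols - comp$center_col)^2 <= comp$size_px^2
  } else {
    abs(rows - comp$center_row) <= comp$size_px &
      abs(cols - comp$center_col) <= comp$size_px
  }
}

gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad <- function(v, n) c(rep(0, n), v, rep(0, n))
  conv1 <- function(v) {
    stats::convolve(pad(v, half), rev(k), type = "filter")
  }
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

stream_seed <- function(master, t_idx, w_idx, v_idx) {
  (as.integer(master) %% 1000000L) * 2000L + t_idx * 101L + w_idx * 17L +
    v_idx * 5L
}

# primary window rates (cps/MBq) for one view at attenuation exp(-mu * depth):
# the conjugate-form spectrum at x = 2 * depth has exactly that factor.
# `cache` memoises by depth (rates are time-independent).
view_primary_rates <- function(components, depth_cm, cache = NULL) {
  if (!is.null(cache)) {
    key <- sprintf("d%.6f", depth_cm)
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  ph <- components$physics
  out <- list(
    th = window_integral(primary_spectrum(ph$lines_th, 2 * depth_cm, ph$coll,
                                          ph$det, ph$att, ph$tau,
                                          low_cutoff_kev = ph$low_cutoff_kev),
                         components$windows),
    ra = window_integral(primary_spectrum(ph$lines_ra, 2 * depth_cm, ph$coll,
                                          ph$det, ph$att, ph$tau,
                                          low_cutoff_kev = ph$low_cutoff_kev),
                         components$windows))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Simulate one conjugate-view acquisition
#'
#' Forward-models the expected counts of every compartment at time `time_d`
#' (activities propagated with [bateman_activities()]), splits the conjugate
#' attenuation between the anterior and posterior views according to each
#' compartment's depth, distributes counts uniformly over the compartment's
#' projected pixels, adds room background, applies the optional spatial
#' blur, and draws independent Poisson counts per pixel, window and view
#' from deterministic per-image streams.
#'
#' @param phantom A [phantom_spec()].
#' @param plan An [acquisition_plan()].
#' @param components A [prepare_components()] bundle at the phantom
#'   thickness (its physics inputs are reused for the per-view attenuation).
#' @param time_d Time since fill (days).
#' @param t_idx Time index used for the random streams.
#' @param b_true,nu_true Scatter scale and coefficients used in the forward
#'   model (defaults 1 and identity, the convention the parametric basis is
#'   calibrated to).
#' @param noise Draw Poisson counts (`TRUE`) or return expected counts
#'   (`FALSE`).
#' @param .rate_cache Internal: environment memoising per-depth primary
#'   rates across time points.
#' @return A list with `ant` and `post` (lists of 4 [planar_image()]s in
#'   window order) and `truth` (tibble of per-compartment activities at
#'   `time_d`).
#' @export
simulate_acquisition <- function(phantom, plan, components, time_d,
                                 t_idx = 1L, b_true = 1,
                                 nu_true = default_scatter_coefficients(),
                                 noise = TRUE, .rate_cache = NULL) {
  if (abs(phantom$x_cm - components$x_cm) > 1e-9) {
    abort("components must be prepared at the phantom thickness")
  }
  dim2 <- c(plan$matrix_dim, plan$matrix_dim)
  nwin <- nrow(plan$windows)
  nu_th <- nu_vector(nu_true, "Th227", plan$windows)
  nu_ra <- nu_vector(nu_true, "Ra223", plan$windows)
  sigma_px <- plan$blur_fwhm_mm / plan$pixel_size_mm / (2 * sqrt(2 * log(2)))

  comps <- phantom$compartments
  truth <- dplyr::bind_cols(
    tibble(label = comps$label),
    purrr::map2_dfr(comps$a_th0, comps$a_ra0,
                    function(th0, ra0) bateman_activities(th0, ra0, time_d)))

  expected <- list(anterior = NULL, posterior = NULL)
  for (view in c("anterior", "posterior")) {
    exp_win <- replicate(nwin, matrix(0, dim2[1], dim2[2]), simplify = FALSE)
    for (i in seq_len(nrow(comps))) {
      comp <- comps[i, ]
      depth <- if (view == "anterior") comp$depth_frac * phantom$x_cm
               else (1 - comp$depth_frac) * phantom$x_cm
      rates <- view_primary_rates(components, depth, .rate_cache)
      a_th <- truth$a_th227[i]
      a_ra <- truth$a_ra223[i]
      scatter <- b_true * (a_th * nu_th * components$s_th +
                           a_ra * nu_ra * components$s_ra)
      win_counts <- plan$duration_s *
        (a_th * rates$th + a_ra * rates$ra + scatter)
      mask <- compartment_mask(comp, dim2)
      npx <- sum(mask)
      for (j in seq_len(nwin)) {
        exp_win[[j]][mask] <- exp_win[[j]][mask] + win_counts[j] / npx
      }
    }
    for (j in seq_len(nwin)) {
      exp_win[[j]] <- gaussian_blur(exp_win[[j]], sigma_px) +
        phantom$room_background_cps[j] * plan$duration_s / prod(dim2)
    }
    expected[[view]] <- exp_win
  }

  images <- purrr::imap(expected, function(exp_win, view) {
    v_idx <- if (view == "anterior") 1L else 2L
    purrr::map(seq_len(nwin), function(j) {
      counts <- exp_win[[j]]
      if (noise) {
        set.seed(stream_seed(plan$seed, t_idx, j, v_idx))
        counts <- matrix(rpois(length(counts), counts), dim2[1], dim2[2])
      }
      planar_image(counts, c(plan$windows$lo_kev[j], plan$windows$hi_kev[j]),
                   view, plan$duration_s, plan$pixel_size_mm,
                   timestamp = time_d)
    })
  })
  list(ant = images$anterior, post = images$posterior, truth = truth)
}

#' Simulate a room-background acquisition
#'
#' Uniform room background imaged for `plan$background_duration_s`
#' (default 9 h), one image per window per view.
#'
#' @inheritParams simulate_acquisition
#' @return List with `ant` and `post` lists of 4 [planar_image()]s.
#' @export
simulate_background <- function(phantom, plan, noise = TRUE) {
  dim2 <- c(plan$matrix_dim, plan$matrix_dim)
  purrr::map(c(anterior = "anterior", posterior = "posterior"), function(view) {
    v_idx <- if (view == "anterior") 1L else 2L
    purrr::map(seq_len(nrow(plan$windows)), function(j) {
      lambda <- phantom$room_background_cps[j] *
        plan$background_duration_s / prod(dim2)
      counts <- matrix(lambda, dim2[1], dim2[2])
      if (noise) {
        set.seed(stream_seed(plan$seed, 999L, j, v_idx))
        counts <- matrix(rpois(prod(dim2), lambda), dim2[1], dim2[2])
      }
      planar_image(counts, c(plan$windows$lo_kev[j], plan$windows$hi_kev[j]),
                   view, plan$background_duration_s, plan$pixel_size_mm,
                   timestamp = "room-background")
    })
  }) |> setNames(c("ant", "post"))
}

#' Simulate a full multi-time-point phantom study
#'
#' Runs [simulate_acquisition()] at every time of the plan (default: the
#' 13-point, 29-day schedule) and a room-background acquisition, and
#' returns the images together with the ground-truth activity table.
#'
#' @inheritParams simulate_acquisition
#' @return A list of class `"phantom_study"`: `acquisitions` (one list per
#'   time point with `ant`, `post`, `truth`), `background`, `truth` (full
#'   table: `time_d`, `label`, `a_th227`, `a_ra223`), `plan`, `phantom`.
#' @export
simulate_timeseries_study <- function(phantom, plan = acquisition_plan(),
                                      components, b_true = 1,
                                      nu_true = default_scatter_coefficients(),
                                      noise = TRUE) {
  rate_cache <- new.env(parent = emptyenv())
  acqs <- purrr::imap(setNames(plan$times_d, plan$times_d), function(t_d, nm) {
    t_idx <- which(plan$times_d == t_d)[1]
    simulate_acquisition(phantom, plan, components, t_d, t_idx,
                         b_true, nu_true, noise, .rate_cache = rate_cache)
  })
  truth <- purrr::map_dfr(acqs, function(a) a$truth)
  structure(list(acquisitions = acqs, background =
                   simulate_background(phantom, plan, noise),
                 truth = dplyr::relocate(truth, "time_d"),
                 plan = plan, phantom = phantom),
            class = "phantom_study")
}
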