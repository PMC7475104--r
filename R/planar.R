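#' Planar gamma-camera image
#'
#' A count image with its acquisition metadata. Counts are non-negative
#' integers as acquired; after background subtraction images become
#' real-valued (no re-rounding).
#'
#' @param counts Matrix of counts (non-negative).
#' @param window Energy window: numeric `c(lo, hi)` in keV or a window name
#'   from [default_windows()].
#' @param view `"anterior"` or `"posterior"`.
#' @param duration_s Acquisition duration (s), > 0.
#' @param pixel_size_mm Pixel size (mm), default 9.59.
#' @param timestamp Acquisition time label (free text or days since fill).
#' @return A list of class `"planar_image"`.
#' @export
planar_image <- function(counts, window, view = c("anterior", "posterior"),
                         duration_s, pixel_size_mm = 9.59, timestamp = NA) {
  view <- match.arg(view)
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (duration_s <= 0) abort("duration_s must be positive")
  if (is.character(window)) {
    wins <- default_windows()
    i <- match(window, wins$window)
    if (is.na(i)) abort(sprintf("unknown window name '%s'", window))
    window <- c(wins$lo_kev[i], wins$hi_kev[i])
  }
  stopifnot(length(window) == 2, window[1] < window[2])
  structure(list(counts = counts, window = window, view = view,
                 duration_s = duration_s, pixel_size_mm = pixel_size_mm,
                 timestamp = timestamp),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %dx%d %s, window %g-%g keV, %g s, total %g counts\n",
              nrow(x$counts), ncol(x$counts), x$view, x$window[1], x$window[2],
              x$duration_s, sum(x$counts)))
  invisible(x)
}

window_name <- function(window, windows = default_windows()) {
  i <- which(abs(windows$lo_kev - window[1]) <= 1 &
               abs(windows$hi_kev - window[2]) <= 1)
  if (length(i) != 1) return(NA_character_)
  windows$window[i]
}

#' Write / read a planar image in the portable text format
#'
#' The portable format is a tab-delimited count matrix `<stem>.tsv` plus a
#' JSON sidecar `<stem>.json` carrying `duration_s`, `view`,
#' `window_lo_kev`, `window_hi_kev`, `pixel_size_mm` and `timestamp`.
#' Reading validates the metadata and snaps the window to the nearest
#' standard acquisition window; a window further than 1 keV from every
#' standard window is rejected.
#'
#' @param img A [planar_image()].
#' @param stem Path stem (without extension).
#' @return `write_planar()` returns `stem` invisibly; `read_planar()`
#'   returns a `planar_image`.
#' @export
write_planar <- function(img, stem) {
  stopifnot(inherits(img, "planar_image"))
  write.table(img$counts, paste0(stem, ".tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- list(duration_s = img$duration_s, view = img$view,
               window_lo_kev = img$window[1], window_hi_kev = img$window[2],
               pixel_size_mm = img$pixel_size_mm,
               timestamp = img$timestamp)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(stem)
}

#' @rdname write_planar
#' @export
read_planar <- function(stem) {
  stem <- sub("\\.(tsv|json)$", "", stem)
  tsv <- paste0(stem, ".tsv")
  json <- paste0(stem, ".json")
  if (!file.exists(tsv)) abort(sprintf("missing image matrix %s", tsv))
  if (!file.exists(json)) abort(sprintf("missing metadata sidecar %s", json))
  meta <- jsonlite::read_json(json)
  for (field in c("duration_s", "view", "window_lo_kev", "window_hi_kev")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("metadata field '%s' missing from %s", field, json))
    }
  }
  counts <- as.matrix(read.delim(tsv, header = FALSE))
  dimnames(counts) <- NULL
  window <- c(meta$window_lo_kev, meta$window_hi_kev)
  if (is.na(window_name(window))) {
    abort(sprintf("window %g-%g keV does not match a standard window within 1 keV",
                  window[1], window[2]))
  }
  wins <- default_windows()
  i <- match(window_name(window), wins$window)
  planar_image(counts, c(wins$lo_kev[i], wins$hi_kev[i]), meta$view,
               meta$duration_s, meta$pixel_size_mm %||% 9.59,
               meta$timestamp %||% NA)
}

#' Subtract the room-background image
#'
#' Scales a long background acquisition (e.g. 9 h) to the image duration
#' (e.g. 20 min, factor 1200/32400) and subtracts it pixelwise, clipping
#' negatives at 0 (clips are reported via a message). The result is
#' real-valued.
#'
#' @param img,bkg [planar_image()]s with matching dimensions and window.
#' @param quiet Suppress the clip message (the clip count is always
#'   recorded in the `"n_clipped"` attribute of the result).
#' @return A `planar_image` with real-valued counts.
#' @export
subtract_room_background <- function(img, bkg, quiet = FALSE) {
  if (!identical(dim(img$counts), dim(bkg$counts))) {
    abort("image and background dimensions differ")
  }
  if (is.na(window_name(img$window)) ||
      !identical(window_name(img$window), window_name(bkg$window))) {
    abort("image and background energy windows differ")
  }
  corrected <- img$counts - bkg$counts * (img$duration_s / bkg$duration_s)
  n_clip <- sum(corrected < 0)
  if (n_clip > 0) {
    if (!quiet) {
      message(sprintf("subtract_room_background: clipped %d negative pixels to 0",
                      n_clip))
    }
    corrected[corrected < 0] <- 0
  }
  out <- img
  out$counts <- corrected
  attr(out, "n_clipped") <- n_clip
  out
}

#' Regions of interest
#'
#' ROIs are defined in 0-based pixel coordinates, (row, col), origin at the
#' top-left. Each ROI carries a paired background ROI of identical shape and
#' size at `center + background_offset`, used by [roi_counts()] to subtract
#' counts from over- and underlying activity. Oversized ROIs (larger than
#' the object) are the intended use, to capture spill-out from the partial
#' volume effect.
#'
#' @param center_px Numeric (row, col), 0-based.
#' @param radius_px Circle radius in pixels (pixels whose centers lie within
#'   the radius are included).
#' @param extent_px Numeric (height, width) of a rectangle in pixels.
#' @param background_offset_px Numeric (row, col) offset of the paired
#'   background ROI.
#' @return A list of class `"roi"`.
#' @export
roi_circle <- function(center_px, radius_px, background_offset_px) {
  stopifnot(length(center_px) == 2, radius_px > 0,
            length(background_offset_px) == 2)
  structure(list(shape = "circle", center_px = center_px,
                 radius_px = radius_px,
                 background_offset_px = background_offset_px),
            class = "roi")
}

#' @rdname roi_circle
#' @export
roi_rect <- function(center_px, extent_px, background_offset_px) {
  stopifnot(length(center_px) == 2, all(extent_px > 0),
            length(background_offset_px) == 2)
  structure(list(shape = "rect", center_px = center_px,
                 extent_px = extent_px,
                 background_offset_px = background_offset_px),
            class = "roi")
}

roi_mask <- function(roi, dim, center = roi$center_px) {
  rows <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  cols <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  if (roi$shape == "circle") {
    m <- (rows - center[1])^2 + (cols - center[2])^2 <= roi$radius_px^2
  } else {
    m <- abs(rows - center[1]) <= roi$extent_px[1] / 2 &
      abs(cols - center[2]) <= roi$extent_px[2] / 2
  }
  m
}

#' Background-corrected ROI counts
#'
#' Sums the pixels in the main ROI and subtracts the sum over the paired
#' identically sized background ROI (correcting for over/underlying
#' activity), clipping the result at 0. The two ROIs must lie within the
#' image and must not overlap.
#'
#' @param img A [planar_image()].
#' @param roi A [roi_circle()] or [roi_rect()].
#' @return Background-corrected counts (scalar).
#' @export
roi_counts <- function(img, roi) {
  d <- dim(img$counts)
  main <- roi_mask(roi, d)
  bkg <- roi_mask(roi, d, center = roi$center_px + roi$background_offset_px)
  in_bounds <- function(center, reach) {
    all(center - reach >= 0) && center[1] + reach <= d[1] - 1 &&
      center[2] + reach <= d[2] - 1
  }
  reach <- if (roi$shape == "circle") roi$radius_px else max(roi$extent_px) / 2
  if (!in_bounds(roi$center_px, reach) ||
      !in_bounds(roi$center_px + roi$background_offset_px, reach)) {
    abort("ROI (or its background pair) extends outside the image")
  }
  if (sum(main) != sum(bkg)) {
    abort("main and background ROI cover different pixel counts")
  }
  if (any(main & bkg)) abort("main and background ROI overlap")
  max(0, sum(img$counts[main]) - sum(img$counts[bkg]))
}

#' Scout-image water-equivalent thickness calibration
#'
#' Fits the empirical mapping from the mean scout-image pixel value p over
#' an ROI to the water-equivalent thickness x (cm), from user-supplied
#' calibration pairs (the mapping, including the couch contribution, is
#' scanner-specific and must be measured with known thicknesses of solid
#' water). The default model is linear in p.
#'
#' @param p Mean scout pixel values of the calibration acquisitions.
#' @param x_cm Known water-equivalent thicknesses (cm).
#' @param degree Polynomial degree of the fit (default 1, linear).
#' @return A list of class `"scout_calibration"` with the fit and the
#'   calibrated p range.
#' @export
scout_calibration <- function(p, x_cm, degree = 1) {
  stopifnot(length(p) == length(x_cm), length(p) >= degree + 1)
  fit <- lm(x_cm ~ stats::poly(p, degree, raw = TRUE))
  structure(list(fit = fit, range_p = range(p), degree = degree),
            class = "scout_calibration")
}

#' @rdname scout_calibration
#' @param cal A `scout_calibration`.
#' @return `scout_thickness()`: thickness in cm.
#' @export
scout_thickness <- function(p, cal) {
  if (any(p < cal$range_p[1] | p > cal$range_p[2])) {
    abort(sprintf("scout pixel value outside calibrated range [%g, %g]",
                  cal$range_p[1], cal$range_p[2]))
  }
  out <- unname(predict(cal$fit, newdata = data.frame(p = p)))
  if (any(out < 0)) abort("calibration yields negative thickness")
  out
}
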