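#' Detection parameters for the circular Hough transform
#'
#' @param radius_min,radius_max Signal radius search range in pixels. The
#'   defaults of 3-12 px correspond to roughly 0.3-1.3 um at a 0.11 um/px
#'   working resolution, the span of dot-like ISH signals.
#' @param sensitivity Detection sensitivity in (0, 1]. The accumulator
#'   acceptance threshold is `vote_floor / sensitivity`, so lowering the
#'   sensitivity monotonically reduces the detection count.
#' @param min_separation Non-maximum suppression radius in pixels (default
#'   twice `radius_min`).
#' @param contrast_channel One of `"dual_pass"` (default: one pass on the
#'   inverted-luminance channel for dark silver dots and one on the red-chroma
#'   channel for red CEP dots, merged and deduplicated), or a single-pass
#'   channel: `"inverted_luminance"`, `"red_chroma"`, `"combined"` (pixelwise
#'   max of both).
#' @param gradient_threshold Minimum edge-gradient magnitude for a pixel to
#'   cast votes.
#' @param vote_floor Accumulator threshold at `sensitivity = 1`.
#' @return A `dq_detection_params` list.
#' @export
detection_params <- function(radius_min = 3, radius_max = 12, sensitivity = 0.5,
                             min_separation = 2 * radius_min,
                             contrast_channel = c("dual_pass", "inverted_luminance",
                                                  "red_chroma", "combined"),
                             gradient_threshold = 0.04, vote_floor = 0.35) {
  contrast_channel <- match.arg(contrast_channel)
  if (radius_min < 1 || radius_min > radius_max) {
    abort("need 1 <= radius_min <= radius_max", class = "dq_param_error")
  }
  if (sensitivity <= 0 || sensitivity > 1) {
    abort("sensitivity must be in (0, 1]", class = "dq_param_error")
  }
  if (min_separation <= 0) abort("min_separation must be > 0", class = "dq_param_error")
  structure(list(radius_min = as.integer(radius_min),
                 radius_max = as.integer(radius_max),
                 sensitivity = sensitivity,
                 min_separation = min_separation,
                 contrast_channel = contrast_channel,
                 gradient_threshold = gradient_threshold,
                 vote_floor = vote_floor),
            class = "dq_detection_params")
}

channel_code <- function(mode) {
  switch(mode, inverted_luminance = 1L, red_chroma = 2L, combined = 3L,
         abort(paste0("unknown contrast channel: ", mode), class = "dq_param_error"))
}

#' Build a scalar contrast channel from an RGB image
#'
#' `inverted_luminance` highlights dark signals (both silver-black gene dots
#' and, to a lesser degree, red CEP dots); `red_chroma` isolates red dots;
#' `combined` is the pixelwise maximum of the two.
#'
#' @param image An [ish_image].
#' @param mode `"inverted_luminance"`, `"red_chroma"` or `"combined"`.
#' @return Numeric matrix (height x width) with values on `[0, 1]`.
#' @export
build_contrast_channel <- function(image, mode = "inverted_luminance") {
  d <- dim(image$pixels)
  cpp_contrast_channel(image$pixels, d[1], d[2], channel_code(mode))
}

#' Detect circular ISH signals
#'
#' Two-stage gradient-voting circular Hough transform: edge pixels vote along
#' their gradient direction for candidate centres over the configured radius
#' range; accumulator peaks above the sensitivity threshold become detections
#' (after non-maximum suppression), and each detection's radius is estimated
#' from the gradient support in its annulus. With the default dual-pass
#' setting the transform runs once on the inverted-luminance channel and once
#' on the red-chroma channel, and the merged detections are deduplicated.
#'
#' @param image A preprocessed [ish_image].
#' @param mask Optional tissue mask ([ish_mask] or [disk_mask]); detections
#'   outside it are discarded. `NULL` keeps everything.
#' @param params A [detection_params] object.
#' @return Tibble of signals with columns `x`, `y`, `radius`, `strength`
#'   (accumulator value), sorted by decreasing strength. The canvas size is
#'   attached as attribute `canvas` (`c(width, height)`).
#' @export
detect_signals <- function(image, mask = NULL, params = detection_params()) {
  if (!inherits(params, "dq_detection_params")) {
    abort("params must come from detection_params()", class = "dq_param_error")
  }
  if (!is.null(mask) && inherits(mask, "ish_mask")) {
    if (!all(dim(mask$mask) == dim(image$pixels)[1:2])) {
      abort("mask dimensions do not match the image", class = "dq_param_error")
    }
  }
  d <- dim(image$pixels)
  vthresh <- params$vote_floor / params$sensitivity
  modes <- if (params$contrast_channel == "dual_pass") {
    c(1L, 2L)
  } else {
    channel_code(params$contrast_channel)
  }
  dets <- lapply(modes, function(m) {
    cpp_hough_raw(image$pixels, d[1], d[2], m,
                  params$radius_min, params$radius_max,
                  params$gradient_threshold, vthresh, params$min_separation)
  })
  m <- do.call(rbind, dets)
  pts <- tibble(x = m[, 1], y = m[, 2], radius = m[, 3], strength = m[, 4])
  if (nrow(pts) > 0) {
    keep <- cpp_nms(pts$x, pts$y, pts$strength, params$min_separation)
    pts <- pts[keep, , drop = FALSE]
    pts <- pts[mask_contains(mask, pts$x, pts$y), , drop = FALSE]
    pts <- arrange(pts, desc(.data$strength), .data$x, .data$y)
  }
  structure(pts, canvas = c(d[2], d[1]), params = params,
            class = class(pts))
}

#' Match detections against planted ground truth
#'
#' Greedy one-to-one matching in decreasing detection-strength order: each
#' detection claims its nearest unclaimed truth point; the pair counts as a
#' match when it lies within `tolerance` pixels. Reports detection precision
#' (matched detections / detections) and recall (matched truth / truth).
#'
#' @param detections Signal tibble (sorted by strength, as returned by
#'   [detect_signals()]).
#' @param truth Tibble of planted points with `x`, `y`.
#' @param tolerance Matching radius in pixels (default 2).
#' @return List with `precision`, `recall`, `matched_detection` (logical per
#'   detection), `truth_index` (matched truth row per detection, `NA` if
#'   unmatched).
#' @export
match_detections <- function(detections, truth, tolerance = 2) {
  if (nrow(detections) == 0 || nrow(truth) == 0) {
    return(list(precision = ifelse(nrow(detections) == 0, NA_real_, 0),
                recall = ifelse(nrow(truth) == 0, NA_real_, 0),
                matched_detection = logical(nrow(detections)),
                truth_index = rep(NA_integer_, nrow(detections))))
  }
  j <- cpp_nearest_unused(detections$x, detections$y, truth$x, truth$y)
  d <- sqrt((truth$x[j] - detections$x)^2 + (truth$y[j] - detections$y)^2)
  ok <- !is.na(j) & d <= tolerance
  list(precision = mean(ok), recall = sum(ok) / nrow(truth),
       matched_detection = ok,
       truth_index = ifelse(ok, j, NA_integer_))
}

#' Read/write signal tables
#'
#' Signals travel as CSV with one row per signal and a required header:
#' `x`, `y`, `radius`, `strength`, and optionally `label`, `label_score`.
#'
#' @param points Signal tibble.
#' @param path CSV path.
#' @return `read_signals_csv` returns the tibble; `write_signals_csv` returns
#'   `path` invisibly.
#' @export
write_signals_csv <- function(points, path) {
  readr::write_csv(points, path)
  invisible(path)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "dq_format_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
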