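#' Region-of-interest and stripe specifications
#'
#' `roi_spec` bundles named voxel sets (pixel index matrices) such as the
#' exposed and enclosed blades of the dentate gyrus and CA3.
#' `stripe_spec` is an ordered voxel sequence anchored at the stimulation
#' electrode, with a per-voxel distance (pixels, or micrometres when a
#' scale is given).
#'
#' @param ... named 2-column matrices (row, col; 1-based) of pixel
#'   coordinates.
#' @return `roi_spec`: a named list of index matrices (class `ecs_rois`).
#' @export
roi_spec <- function(...) {
  rois <- list(...)
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop_ecs("malformed_input", "all ROIs must be named")
  rois <- lapply(rois, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop_ecs("malformed_input", "ROI must be (row, col) pairs")
    storage.mode(m) <- "integer"
    m
  })
  structure(rois, class = "ecs_rois")
}

#' @rdname roi_spec
#' @param origin electrode position, `c(row, col)`.
#' @param pixels ordered 2-column matrix of voxel coordinates along the
#'   stripe (first voxel nearest the electrode).
#' @param scale_um_per_px optional pixel size; distances are reported in
#'   micrometres when given, else in pixels.
#' @return `stripe_spec`: list with `origin`, `pixels`, `distance`
#'   (class `ecs_stripe`).
#' @export
stripe_spec <- function(origin, pixels, scale_um_per_px = NULL) {
  pixels <- as.matrix(pixels)
  d <- sqrt((pixels[, 1] - origin[1])^2 + (pixels[, 2] - origin[2])^2)
  if (is.unsorted(d))
    stop_ecs("malformed_input", "stripe voxels must be ordered outward from the electrode")
  if (!is.null(scale_um_per_px)) d <- d * scale_um_per_px
  structure(list(origin = origin, pixels = pixels, distance = d,
                 unit = if (is.null(scale_um_per_px)) "px" else "um"),
            class = "ecs_stripe")
}

.roi_check <- function(pix, d) {
  if (nrow(pix) == 0L) stop_ecs("malformed_input", "empty ROI")
  if (any(pix[, 1] < 1L | pix[, 1] > d[1] | pix[, 2] < 1L | pix[, 2] > d[2]))
    stop_ecs("malformed_input", "ROI indices outside the frame")
}

# mean dF/F trace over the voxels of one ROI
.roi_trace <- function(dff, pix) {
  d <- dim(dff$values)
  .roi_check(pix, d)
  M <- matrix(dff$values, d[1] * d[2], d[3])
  lin <- (pix[, 2] - 1L) * d[1] + pix[, 1]
  colMeans(M[lin, , drop = FALSE], na.rm = TRUE)
}

#' Integral (area under the curve) of the dF/F response in an ROI
#'
#' Trapezoidal area of the dF/F trace over the analysis window, per voxel,
#' averaged across the voxels of the ROI. The default window runs from
#' stimulus onset to the end of the recording.
#'
#' @param dff an [compute_dff()] result (usually filtered).
#' @param roi a 2-column pixel matrix or an [roi_spec()] (then a named
#'   vector is returned).
#' @param window frame range `c(first, last)` (1-based, inclusive);
#'   `NULL` for stimulus onset to last frame.
#' @return Integral in %*ms (named vector for an `ecs_rois`).
#' @export
roi_integral <- function(dff, roi, window = NULL) {
  if (inherits(roi, "ecs_rois"))
    return(vapply(roi, function(m) roi_integral(dff, m, window), numeric(1)))
  d <- dim(dff$values)
  if (is.null(window)) window <- c(dff$stim_frames[1], d[3])
  if (window[1] < 1L || window[2] > d[3] || window[1] >= window[2])
    stop_ecs("malformed_input", "window outside the movie")
  tr <- .roi_trace(dff, roi)[window[1]:window[2]]
  dt <- dff$frame_interval_ms
  sum((tr[-1] + tr[-length(tr)]) / 2) * dt
}

#' Activated area: pixels above the dF/F threshold
#'
#' Number of pixels whose post-stimulus peak dF/F strictly exceeds the
#' threshold (0.05% by default).
#'
#' @param dff a (filtered) [compute_dff()] result.
#' @param threshold %% dF/F.
#' @return Integer pixel count.
#' @export
activated_area <- function(dff, threshold = 0.05) {
  d <- dim(dff$values)
  post <- seq.int(dff$stim_frames[1], d[3])
  M <- matrix(dff$values, d[1] * d[2], d[3])[, post, drop = FALSE]
  pk <- apply(M, 1L, max)
  sum(pk > threshold, na.rm = TRUE)
}

#' Paired-pulse ratio per blade
#'
#' Maximal amplitude of the second-pulse response divided by the first,
#' for the mean trace of each ROI (blade), plus the slice mean over the
#' blades. In the default (`baseline_corrected`) mode the second-pulse
#' amplitude is measured relative to the dF/F level immediately before
#' the second stimulus, separating the overlapping responses; the
#' `absolute` mode uses the raw peak instead.
#'
#' @param dff a (filtered) [compute_dff()] result whose `stim_frames`
#'   holds both pulse frames.
#' @param blades an [roi_spec()] with one entry per blade.
#' @param mode `"baseline_corrected"` or `"absolute"`.
#' @return List with `per_blade` (named vector) and `slice_mean`.
#' @export
paired_pulse_ratio <- function(dff, blades,
                               mode = c("baseline_corrected", "absolute")) {
  mode <- match.arg(mode)
  if (length(dff$stim_frames) < 2L)
    stop_ecs("malformed_input", "paired-pulse ratio needs two stimulus frames")
  s1 <- dff$stim_frames[1]; s2 <- dff$stim_frames[2]
  nt <- dim(dff$values)[3]
  w2_end <- min(nt, s2 + (s2 - s1) - 1L)
  ppr <- vapply(blades, function(pix) {
    tr <- .roi_trace(dff, pix)
    a1 <- max(tr[s1:(s2 - 1L)])
    pre2 <- tr[s2 - 1L]
    a2raw <- max(tr[s2:w2_end])
    if (a1 <= 0) stop_ecs("undefined_ppr", "first-pulse amplitude <= 0")
    a2 <- if (mode == "baseline_corrected") a2raw - pre2 else a2raw
    a2 / a1
  }, numeric(1))
  list(per_blade = ppr, slice_mean = mean(ppr))
}

#' Signal profile along a stripe of voxels
#'
#' The chosen metric (post-stimulus peak or integral) for each voxel along
#' an electrode-anchored stripe, ordered by distance. Voxels outside the
#' movie are dropped with a warning.
#'
#' @param dff a (filtered) [compute_dff()] result.
#' @param stripe an [stripe_spec()].
#' @param metric `"peak"` or `"integral"`.
#' @param window frame range; `NULL` for stimulus onset to last frame.
#' @return data.frame with `distance` and `value`, ordered by distance.
#' @export
stripe_profile <- function(dff, stripe, metric = c("peak", "integral"),
                           window = NULL) {
  metric <- match.arg(metric)
  d <- dim(dff$values)
  pix <- stripe$pixels
  inside <- pix[, 1] >= 1L & pix[, 1] <= d[1] & pix[, 2] >= 1L & pix[, 2] <= d[2]
  if (!all(inside)) {
    warn_ecs("stripe_truncated", "%d stripe voxel(s) outside the movie dropped",
             sum(!inside))
    pix <- pix[inside, , drop = FALSE]
  }
  if (is.null(window)) window <- c(dff$stim_frames[1], d[3])
  M <- matrix(dff$values, d[1] * d[2], d[3])
  lin <- (pix[, 2] - 1L) * d[1] + pix[, 1]
  sub <- M[lin, window[1]:window[2], drop = FALSE]
  val <- if (metric == "peak") {
    apply(sub, 1L, max)
  } else {
    dt <- dff$frame_interval_ms
    apply(sub, 1L, function(tr) sum((tr[-1] + tr[-length(tr)]) / 2) * dt)
  }
  data.frame(distance = stripe$distance[inside], value = val)
}
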