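#' Side-view synapse ROI
#'
#' Defines the 1 um x 250 nm profile geometry across a bar-like scaffold:
#' the bar center, and the unit normal to the bar's long axis, signed so
#' that + points toward the presynaptic vesicle cloud.
#'
#' @param bar_center_nm length-2 (x, y) in nm.
#' @param axis_normal length-2 unit vector perpendicular to the bar
#'   (normalized here); + side = presynaptic.
#' @param profile_length_nm profile length, default 1000 nm.
#' @param profile_width_nm averaging width across the profile, default
#'   250 nm.
#' @param source `"manual"` or `"auto"`.
#' @param id optional identifier used in error messages and outputs.
#' @return an object of class `sideview_roi`.
#' @export
sideview_roi <- function(bar_center_nm, axis_normal,
                         profile_length_nm = 1000,
                         profile_width_nm = 250,
                         source = c("manual", "auto"),
                         id = NULL) {
  source <- match.arg(source)
  stopifnot(length(bar_center_nm) == 2, length(axis_normal) == 2,
            profile_length_nm > 0, profile_width_nm > 0)
  structure(
    list(bar_center_nm = as.numeric(bar_center_nm),
         axis_normal = unit2(as.numeric(axis_normal)),
         profile_length_nm = profile_length_nm,
         profile_width_nm = profile_width_nm,
         source = source, id = id),
    class = "sideview_roi")
}

## ROI straight from a ground-truth table row: normal = perp(orientation)
## signed toward the presynaptic cloud side
roi_from_truth <- function(truth_row, profile_length_nm = 1000,
                           profile_width_nm = 250) {
  u <- c(truth_row$orient_x, truth_row$orient_y)
  nv <- perp2(u) * truth_row$cloud_side
  sideview_roi(c(truth_row$center_x_nm, truth_row$center_y_nm), nv,
               profile_length_nm, profile_width_nm, source = "manual",
               id = truth_row$synapse)
}

#' Read manually drawn side-view ROIs from CSV
#'
#' One row per synapse: `image`, `x1`, `y1`, `x2`, `y2` (nm; the line is
#' drawn across the bar from the postsynaptic toward the presynaptic
#' side, so the + direction of the profile is presynaptic), `culture`,
#' `genotype`.
#'
#' @param path CSV path.
#' @param profile_length_nm,profile_width_nm profile geometry.
#' @return a list of `sideview_roi`, with `image`, `culture`, `genotype`
#'   carried in an attribute data frame `meta`.
#' @export
read_roi_csv <- function(path, profile_length_nm = 1000,
                         profile_width_nm = 250) {
  d <- utils::read.csv(path)
  need <- c("image", "x1", "y1", "x2", "y2", "culture", "genotype")
  if (!all(need %in% names(d)))
    stop("ROI CSV must have columns: ", paste(need, collapse = ", "))
  rois <- lapply(seq_len(nrow(d)), function(i) {
    p1 <- c(d$x1[i], d$y1[i]); p2 <- c(d$x2[i], d$y2[i])
    sideview_roi((p1 + p2) / 2, p2 - p1, profile_length_nm,
                 profile_width_nm, source = "manual", id = i)
  })
  attr(rois, "meta") <- d[, c("image", "culture", "genotype")]
  rois
}

#' Extract a perpendicular intensity profile across a scaffold bar
#'
#' Samples every channel along the ROI's signed normal on a regular grid
#' (step = one pixel), averaging across the profile width perpendicular to
#' it, with bilinear interpolation. Position 0 is the bar center; positive
#' positions point toward the presynapse. The profile is returned
#' unsmoothed.
#'
#' @param scene a `synthetic_scene`, or a named list of channel matrices
#'   (then `pixel_size_nm` must be given).
#' @param roi a [sideview_roi()]; must lie fully inside the image.
#' @param pixel_size_nm pixel pitch; taken from the scene when omitted.
#' @return a data frame of class `line_profile`: `position_nm` plus one
#'   intensity column per channel; attributes `pixel_size_nm`, `roi`,
#'   `smoothed` (FALSE), `smoothing_window_px` (NA).
#' @export
extract_profile <- function(scene, roi, pixel_size_nm = NULL) {
  stopifnot(inherits(roi, "sideview_roi"))
  if (inherits(scene, "synthetic_scene")) {
    channels <- scene$channels
    pixel_size_nm <- pixel_size_nm %||% scene$pixel_size_nm
  } else {
    channels <- scene
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required")
  }
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  px <- pixel_size_nm
  nr <- nrow(channels[[1]]); nc <- ncol(channels[[1]])
  dvec <- roi$axis_normal                  # along the profile
  wvec <- perp2(dvec)                      # across it (bar direction)
  half_l <- roi$profile_length_nm / 2
  half_w <- roi$profile_width_nm / 2
  tpos <- seq(-half_l, half_l, by = px)
  spos <- seq(-half_w, half_w, by = px)
  ## all sample points: outer(t, s)
  xp <- roi$bar_center_nm[1] + outer(tpos, rep(1, length(spos))) * dvec[1] +
    outer(rep(1, length(tpos)), spos) * wvec[1]
  yp <- roi$bar_center_nm[2] + outer(tpos, rep(1, length(spos))) * dvec[2] +
    outer(rep(1, length(tpos)), spos) * wvec[2]
  if (min(xp) < 0 || min(yp) < 0 ||
      max(xp) > (nc - 1) * px || max(yp) > (nr - 1) * px)
    stop("ROI ", roi$id %||% "(unnamed)",
         " exceeds image bounds: profile cannot be extracted")
  xg <- (seq_len(nc) - 1) * px
  yg <- (seq_len(nr) - 1) * px
  out <- data.frame(position_nm = tpos)
  for (nm in names(channels)) {
    v <- pracma::interp2(xg, yg, channels[[nm]], as.vector(xp),
                         as.vector(yp), method = "linear")
    out[[nm]] <- rowMeans(matrix(v, length(tpos), length(spos)))
  }
  structure(out, pixel_size_nm = px, roi = roi, smoothed = FALSE,
            smoothing_window_px = NA_integer_,
            class = c("line_profile", "data.frame"))
}

#' Apply the rolling average to a line profile
#'
#' Centered moving mean over `k` samples (default 5 pixels) applied to
#' every channel column; the ends use shrinking windows (mean over the
#' samples available) rather than padding.
#'
#' @param profile a `line_profile`.
#' @param k window in samples (pixels); odd, >= 1.
#' @return the smoothed `line_profile` (`smoothed` attribute set, window
#'   recorded both in pixels and nm).
#' @export
smooth_profile <- function(profile, k = 5) {
  stopifnot(inherits(profile, "line_profile"), k >= 1, k %% 2 == 1)
  out <- profile
  for (nm in setdiff(names(profile), "position_nm"))
    out[[nm]] <- rolling_mean(profile[[nm]], k)
  attr(out, "smoothed") <- TRUE
  attr(out, "smoothing_window_px") <- as.integer(k)
  attr(out, "smoothing_window_nm") <- k * attr(profile, "pixel_size_nm")
  out
}

#' @export
print.line_profile <- function(x, ...) {
  cat("line_profile:", nrow(x), "positions,",
      sprintf("[%g, %g] nm,", min(x$position_nm), max(x$position_nm)),
      "channels:", paste(setdiff(names(x), "position_nm"), collapse = ", "))
  if (isTRUE(attr(x, "smoothed")))
    cat(" (smoothed, k =", attr(x, "smoothing_window_px"), "px)")
  cat("\n")
  invisible(x)
}
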