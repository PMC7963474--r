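#' Puncta segmentation parameters
#'
#' @param threshold_method `"otsu"`, `"isodata"`, or `"fixed"` (which
#'   requires `threshold_value`).
#' @param min_area_um2,max_area_um2 inclusive area bounds of retained
#'   puncta; defaults 0.4 and 2 square micrometers.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param threshold_value fixed threshold in counts, for
#'   `threshold_method = "fixed"`.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "isodata",
                                                     "fixed"),
                                min_area_um2 = 0.4,
                                max_area_um2 = 2,
                                connectivity = 8,
                                threshold_value = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2))
    stop("need 0 < min_area_um2 < max_area_um2")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (threshold_method == "fixed" && is.null(threshold_value))
    stop("threshold_method = 'fixed' requires threshold_value")
  structure(
    list(threshold_method = threshold_method,
         min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
         connectivity = as.integer(connectivity),
         threshold_value = threshold_value),
    class = "segmentation_params")
}

## ImageJ-style IsoData (iterative intermeans) threshold
isodata_threshold <- function(x) {
  t_old <- mean(range(x))
  for (it in 1:200) {
    lo <- x[x <= t_old]; hi <- x[x > t_old]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 1e-8 * diff(range(x))) return(t_new)
    t_old <- t_new
  }
  t_old
}

#' Automatic foreground threshold
#'
#' Computes a global threshold (Otsu by default, IsoData/intermeans as the
#' ImageJ-default alternative, or a fixed value) and returns the binary
#' foreground mask. A constant image yields an empty mask with a warning,
#' never an error. The threshold used is attached as
#' `attr(mask, "threshold")` so run logs can report it.
#'
#' @param image single-channel numeric matrix.
#' @param method `"otsu"`, `"isodata"` or `"fixed"`.
#' @param value threshold in counts when `method = "fixed"`.
#' @return logical matrix (`TRUE` = foreground) with attributes
#'   `threshold` and `method`.
#' @export
auto_threshold <- function(image, method = c("otsu", "isodata", "fixed"),
                           value = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), length(image) > 0)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: empty mask returned")
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "method") <- method
    return(mask)
  }
  th <- switch(method,
    otsu = EBImage::otsu(image, range = rng, levels = 256),
    isodata = isodata_threshold(image),
    fixed = {
      if (is.null(value)) stop("method = 'fixed' requires value")
      value
    })
  mask <- image > th
  attr(mask, "threshold") <- th
  attr(mask, "method") <- method
  mask
}

#' Connected-component labeling with selectable connectivity
#'
#' Iterative minimum-label propagation over 4- or 8-neighborhoods.
#' Labels are renumbered 1..n in order of first (row-major) occurrence,
#' so output is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(lab)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  big <- .Machine$integer.max
  repeat {
    cur <- ifelse(mask, lab, big)
    best <- cur
    for (s in shifts) {
      shifted <- matrix(big, nr, nc)
      r_src <- seq_len(nr) - s[1]; c_src <- seq_len(nc) - s[2]
      r_ok <- r_src >= 1 & r_src <= nr; c_ok <- c_src >= 1 & c_src <= nc
      shifted[r_ok, c_ok] <- cur[r_src[r_ok], c_src[c_ok]]
      best <- pmin(best, shifted)
    }
    best[!mask] <- big
    if (all(best[mask] == lab[mask])) break
    lab[mask] <- best[mask]
  }
  ## renumber by first occurrence, column-major order (R storage order)
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

#' Detect synaptic puncta with the 0.4-2 um^2 size filter
#'
#' Thresholds the image, labels connected components, keeps those whose
#' area lies inclusively within `[min_area_um2, max_area_um2]`, and
#' tabulates per-punctum and per-image statistics. Density is reported per
#' 100 square micrometers of imaged field (the per-image normalization is
#' recorded in the attributes).
#'
#' @param image single-channel numeric matrix (counts).
#' @param params a [segmentation_params()].
#' @param pixel_size_nm pixel pitch in nm; required, since areas are
#'   converted to square micrometers.
#' @return a data frame of class `puncta_table` with one row per retained
#'   punctum (`label`, `area_um2`, `centroid_x_nm`, `centroid_y_nm`,
#'   `mean_intensity`, `peak_intensity`) and attributes `summary`
#'   (count, density per 100 um^2, mean area, mean intensity — `NA` means
#'   when no puncta), `threshold`, `field_area_um2`,
#'   `density_normalization`.
#' @export
detect_puncta <- function(image, params = segmentation_params(),
                          pixel_size_nm) {
  stopifnot(inherits(params, "segmentation_params"))
  if (missing(pixel_size_nm) || is.null(pixel_size_nm) ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm is required to convert areas to um^2")
  mask <- auto_threshold(image, params$threshold_method,
                         params$threshold_value)
  lab <- label_components(mask, params$connectivity)
  px_area_um2 <- (pixel_size_nm / 1000)^2
  field_area_um2 <- length(image) * px_area_um2

  keep_tab <- NULL
  if (max(lab) > 0) {
    n_px <- tabulate(lab[lab > 0], nbins = max(lab))
    area <- n_px * px_area_um2
    keep <- which(area >= params$min_area_um2 - 1e-12 &
                  area <= params$max_area_um2 + 1e-12)
    if (length(keep) > 0) {
      rows <- lapply(seq_along(keep), function(i) {
        id <- keep[i]
        idx <- which(lab == id, arr.ind = TRUE)
        vals <- image[lab == id]
        data.frame(label = i,
                   area_um2 = area[id],
                   centroid_x_nm = (mean(idx[, 2]) - 1) * pixel_size_nm,
                   centroid_y_nm = (mean(idx[, 1]) - 1) * pixel_size_nm,
                   mean_intensity = mean(vals),
                   peak_intensity = max(vals))
      })
      keep_tab <- do.call(rbind, rows)
    }
  }
  if (is.null(keep_tab))
    keep_tab <- data.frame(label = integer(), area_um2 = numeric(),
                           centroid_x_nm = numeric(),
                           centroid_y_nm = numeric(),
                           mean_intensity = numeric(),
                           peak_intensity = numeric())
  n <- nrow(keep_tab)
  summ <- data.frame(
    count = n,
    density_per_100um2 = n / field_area_um2 * 100,
    mean_area_um2 = if (n > 0) mean(keep_tab$area_um2) else NA_real_,
    mean_intensity = if (n > 0) mean(keep_tab$mean_intensity) else NA_real_)
  structure(keep_tab,
            summary = summ,
            threshold = attr(mask, "threshold"),
            field_area_um2 = field_area_um2,
            density_normalization = "per 100 um^2 of imaged field",
            params = params,
            class = c("puncta_table", "data.frame"))
}

#' @export
print.puncta_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat("puncta_table:", s$count, "puncta;",
      sprintf("density %.3f / 100 um^2;", s$density_per_100um2),
      if (s$count > 0)
        sprintf("mean area %.3f um^2; mean intensity %.1f",
                s$mean_area_um2, s$mean_intensity) else "", "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' Mean level of an image within a binary mask
#'
#' Mask-based confocal level measurement: the mean intensity of `image`
#' over the foreground pixels of `mask` (typically generated by
#' [auto_threshold()] on a reference channel).
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same dimensions.
#' @return the mean level; `NA` with a warning for an empty mask.
#' @export
measure_within_mask <- function(image, mask) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  mask <- mask & !is.na(mask)
  if (!any(mask)) {
    warning("empty mask: returning NA")
    return(NA_real_)
  }
  mean(image[mask])
}
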