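## per-component shape moments: centroid (nm), principal-axis orientation,
## elongation (sqrt of eigenvalue ratio) and a length estimate
## (sqrt(12 * leading eigenvalue): exact for an ideal uniform bar)
component_moments <- function(lab, pixel_size_nm) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    x <- (idx[, 2] - 1) * pixel_size_nm
    y <- (idx[, 1] - 1) * pixel_size_nm
    n <- length(x)
    ## + px^2/12 on the diagonal accounts for finite pixel extent
    cv <- stats::cov(cbind(x, y)) * (n - 1) / n +
      diag(pixel_size_nm^2 / 12, 2)
    if (n == 1) cv <- diag(pixel_size_nm^2 / 12, 2)
    e <- eigen(cv, symmetric = TRUE)
    data.frame(id = id, n_px = n,
               cx = mean(x), cy = mean(y),
               ux = e$vectors[1, 1], uy = e$vectors[2, 1],
               elongation = sqrt(e$values[1] / max(e$values[2], 1e-12)),
               length_nm = sqrt(12 * e$values[1]))
  })
  do.call(rbind, rows)
}

#' Automatic detection of side-view synapse candidates
#'
#' Emulates the manual selection rule: a side-view synapse is a single
#' bar-like scaffold structure lying along the edge of a vesicle cluster.
#' The scaffold channel is thresholded and labeled; components are kept
#' as bars when their elongation (major/minor axis ratio) reaches
#' `elongation_min` and their length falls within `bar_length_range_nm`.
#' A bar becomes a candidate when its centroid lies within
#' `adjacency_max_nm` of exactly one vesicle-cluster boundary; bars
#' adjacent to two or more clusters, and clusters claimed by two or more
#' bars, are rejected ("single bar-like structure"). The profile normal is
#' the bar's minor axis, signed toward the adjacent cluster centroid.
#'
#' @param scaffold,vesicle channel matrices sharing geometry.
#' @param pixel_size_nm pixel pitch, nm.
#' @param elongation_min minimum major/minor axis ratio, default 2.
#' @param adjacency_max_nm maximum centroid-to-cluster-boundary distance,
#'   default 200 nm.
#' @param bar_length_range_nm admissible bar lengths, default 200-800 nm.
#' @param threshold_method threshold for both channels, default Otsu.
#' @param min_cloud_area_um2 vesicle components smaller than this are
#'   ignored as noise; default 0.05.
#' @param profile_length_nm,profile_width_nm geometry of the returned ROIs.
#' @return list of [sideview_roi()] (source `"auto"`), with a diagnostics
#'   data frame in `attr(, "candidates")`.
#' @export
detect_sideview_candidates <- function(scaffold, vesicle, pixel_size_nm,
                                       elongation_min = 2,
                                       adjacency_max_nm = 200,
                                       bar_length_range_nm = c(200, 800),
                                       threshold_method = "otsu",
                                       min_cloud_area_um2 = 0.05,
                                       profile_length_nm = 1000,
                                       profile_width_nm = 250) {
  stopifnot(all(dim(scaffold) == dim(vesicle)), pixel_size_nm > 0)
  sc_lab <- label_components(auto_threshold(scaffold, threshold_method), 8)
  ve_lab <- label_components(auto_threshold(vesicle, threshold_method), 8)
  if (max(ve_lab) == 0) return(structure(list(), candidates = NULL))
  px_area_um2 <- (pixel_size_nm / 1000)^2
  clouds <- component_moments(ve_lab, pixel_size_nm)
  clouds <- clouds[clouds$n_px * px_area_um2 >= min_cloud_area_um2, ,
                   drop = FALSE]
  if (nrow(clouds) == 0) return(structure(list(), candidates = NULL))
  if (max(sc_lab) == 0) return(structure(list(), candidates = NULL))
  bars <- component_moments(sc_lab, pixel_size_nm)
  bars$is_bar <- bars$elongation >= elongation_min &
    bars$length_nm >= bar_length_range_nm[1] &
    bars$length_nm <= bar_length_range_nm[2]

  ## distance from each bar centroid to the nearest pixel of each cloud
  cloud_px <- lapply(clouds$id, function(id) {
    idx <- which(ve_lab == id, arr.ind = TRUE)
    cbind((idx[, 2] - 1) * pixel_size_nm, (idx[, 1] - 1) * pixel_size_nm)
  })
  bars$n_adjacent <- 0L
  bars$cloud <- NA_integer_
  for (i in seq_len(nrow(bars))) {
    if (!bars$is_bar[i]) next
    d <- vapply(cloud_px, function(p)
      sqrt(min((p[, 1] - bars$cx[i])^2 + (p[, 2] - bars$cy[i])^2)), 0)
    adj <- which(d <= adjacency_max_nm)
    bars$n_adjacent[i] <- length(adj)
    if (length(adj) == 1) bars$cloud[i] <- adj
  }
  ## clusters claimed by >= 2 bars invalidate those bars
  claimed <- table(bars$cloud[!is.na(bars$cloud)])
  shared <- as.integer(names(claimed)[claimed >= 2])
  bars$accepted <- bars$is_bar & bars$n_adjacent == 1 &
    !(bars$cloud %in% shared)

  rois <- lapply(which(bars$accepted), function(i) {
    n0 <- perp2(c(bars$ux[i], bars$uy[i]))
    cc <- clouds[bars$cloud[i], ]
    s <- sign(sum(n0 * c(cc$cx - bars$cx[i], cc$cy - bars$cy[i])))
    if (s == 0) s <- 1
    sideview_roi(c(bars$cx[i], bars$cy[i]), s * n0,
                 profile_length_nm, profile_width_nm,
                 source = "auto", id = bars$id[i])
  })
  structure(rois, candidates = bars)
}
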