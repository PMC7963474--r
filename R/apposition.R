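#' Peak-to-peak apposition measurement on a smoothed profile
#'
#' Locates the scaffold peak as the global maximum of the scaffold channel
#' (ties broken toward position 0, with a warning), then the protein peak
#' as the maximum of the protein channel within +/- `window_nm`
#' (inclusive) of the scaffold peak. The signed distance is
#' `protein peak - scaffold peak` along the + (presynaptic) direction of
#' the profile. `window_truncated` is set when the protein maximum sits at
#' an edge of the search window, i.e. the true peak may lie beyond it.
#'
#' @param profile a smoothed `line_profile` (a warning is issued if the
#'   smoothing flag is not set).
#' @param scaffold,protein channel column names.
#' @param window_nm half-width of the peak-search window, default 100 nm.
#' @return an object of class `sideview_measurement`: scaffold_peak_nm,
#'   protein_peak_nm, protein_peak_intensity, distance_nm,
#'   window_truncated, positive (NA until classified).
#' @export
measure_apposition <- function(profile, scaffold = "scaffold",
                               protein = "protein", window_nm = 100) {
  stopifnot(inherits(profile, "line_profile"),
            scaffold %in% names(profile), protein %in% names(profile),
            window_nm > 0)
  if (!isTRUE(attr(profile, "smoothed")))
    warning("profile is not smoothed; peak positions are noise-sensitive")
  pos <- profile$position_nm
  sc <- profile[[scaffold]]
  tol <- 1e-9 * max(abs(sc), 1)
  peak_idx <- which(sc >= max(sc) - tol)
  if (length(peak_idx) > 1) {
    warning("tied scaffold maxima; choosing the one nearest position 0")
    peak_idx <- peak_idx[which.min(abs(pos[peak_idx]))]
  }
  sc_pos <- pos[peak_idx]

  in_win <- which(abs(pos - sc_pos) <= window_nm + 1e-9)
  pr <- profile[[protein]][in_win]
  ptol <- 1e-9 * max(abs(pr), 1)
  p_idx <- in_win[pr >= max(pr) - ptol]
  if (length(p_idx) > 1)
    p_idx <- p_idx[which.min(abs(pos[p_idx]))]   # ties toward position 0
  pr_pos <- pos[p_idx]
  truncated <- p_idx == in_win[1] || p_idx == in_win[length(in_win)]

  structure(
    list(scaffold_peak_nm = sc_pos,
         protein_peak_nm = pr_pos,
         protein_peak_intensity = profile[[protein]][p_idx],
         scaffold_peak_intensity = sc[peak_idx],
         distance_nm = pr_pos - sc_pos,
         window_nm = window_nm,
         window_truncated = truncated,
         positive = NA),
    class = "sideview_measurement")
}

#' @export
print.sideview_measurement <- function(x, ...) {
  cat(sprintf(
    "sideview_measurement: scaffold peak %+g nm, protein peak %+g nm, distance %+g nm%s\n",
    x$scaffold_peak_nm, x$protein_peak_nm, x$distance_nm,
    if (x$window_truncated) " [window truncated]" else ""))
  invisible(x)
}

#' Align profiles to the scaffold peak and average
#'
#' Shifts each smoothed profile so its scaffold peak sits at position 0,
#' resamples every channel onto a common grid (linear interpolation,
#' step = the profiles' sampling step), and returns mean, SEM
#' (sample SD / sqrt(n)) and contributing n per position and channel.
#'
#' @param profiles list of smoothed `line_profile`s sharing one step size.
#' @param scaffold alignment channel name.
#' @return an object of class `average_profile`: a long-format data frame
#'   (`position_nm`, `channel`, `mean`, `sem`, `n`) with attribute
#'   `n_synapses`. With fewer than 2 profiles the SEM is `NA`.
#' @export
align_and_average <- function(profiles, scaffold = "scaffold") {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "line_profile")))
  steps <- vapply(profiles, function(p) stats::median(diff(p$position_nm)),
                  0)
  if (max(steps) - min(steps) > 1e-6)
    stop("profiles must share a common sampling step")
  step <- steps[1]
  channels <- setdiff(names(profiles[[1]]), "position_nm")
  shifted <- lapply(profiles, function(p) {
    m <- measure_apposition(p, scaffold = scaffold,
                            protein = channels[1], window_nm = Inf)
    data.frame(position_nm = p$position_nm - m$scaffold_peak_nm,
               p[channels])
  })
  lo <- min(vapply(shifted, function(p) min(p$position_nm), 0))
  hi <- max(vapply(shifted, function(p) max(p$position_nm), 0))
  grid <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
  out <- list()
  for (ch in channels) {
    vals <- vapply(shifted, function(p)
      stats::approx(p$position_nm, p[[ch]], xout = grid, rule = 1)$y,
      numeric(length(grid)))
    vals <- matrix(vals, nrow = length(grid))
    n <- rowSums(!is.na(vals))
    mu <- rowMeans(vals, na.rm = TRUE)
    sdv <- apply(vals, 1, function(r) stats::sd(r, na.rm = TRUE))
    semv <- ifelse(n >= 2, sdv / sqrt(n), NA_real_)
    out[[ch]] <- data.frame(position_nm = grid, channel = ch,
                            mean = mu, sem = semv, n = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, n_synapses = length(profiles),
            class = c("average_profile", "data.frame"))
}

#' @export
print.average_profile <- function(x, ...) {
  cat("average_profile:", attr(x, "n_synapses"), "synapses;",
      length(unique(x$channel)), "channel(s);",
      sprintf("positions [%g, %g] nm\n", min(x$position_nm),
              max(x$position_nm)))
  invisible(x)
}

#' @export
plot.average_profile <- function(x, channels = unique(x$channel), ...) {
  cols <- seq_along(channels) + 1
  rng <- range(x$mean + ifelse(is.na(x$sem), 0, x$sem),
               x$mean - ifelse(is.na(x$sem), 0, x$sem), na.rm = TRUE)
  plot(NA, xlim = range(x$position_nm), ylim = rng,
       xlab = "position relative to scaffold peak (nm)",
       ylab = "intensity (counts)", ...)
  for (i in seq_along(channels)) {
    d <- x[x$channel == channels[i], ]
    graphics::lines(d$position_nm, d$mean, col = cols[i], lwd = 2)
    ok <- !is.na(d$sem)
    graphics::arrows(d$position_nm[ok], d$mean[ok] - d$sem[ok],
                     d$position_nm[ok], d$mean[ok] + d$sem[ok],
                     length = 0, col = grDevices::adjustcolor(cols[i], 0.4))
  }
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = channels, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Knockout-referenced positivity classification
#'
#' A synapse is called positive when its protein peak intensity is
#' strictly higher than `mean + n_sd * SD` of the knockout reference
#' peaks, with the threshold computed separately within each culture
#' (sample SD, n-1 denominator). Cultures with fewer than 2 reference
#' values cannot form a threshold; their synapses are flagged
#' undetermined (`NA`) with a warning.
#'
#' @param peaks numeric, protein peak intensities of the synapses to
#'   classify.
#' @param culture culture id per synapse (recycled if length 1).
#' @param ko_peaks numeric, knockout reference peak intensities.
#' @param ko_culture culture id per reference value (recycled if length 1).
#' @param n_sd threshold stringency in SDs, default 3.
#' @return an object of class `positivity_result`: `calls` data frame
#'   (`peak`, `culture`, `threshold`, `positive`), `thresholds` per
#'   culture, `fraction_positive` pooled over determined calls,
#'   `fraction_by_culture`, `n_undetermined`.
#' @export
classify_positive <- function(peaks, culture = "1", ko_peaks,
                              ko_culture = "1", n_sd = 3) {
  stopifnot(length(peaks) >= 1, length(ko_peaks) >= 1)
  culture <- rep_len(as.character(culture), length(peaks))
  ko_culture <- rep_len(as.character(ko_culture), length(ko_peaks))
  cultures <- sort(unique(culture))
  thr <- vapply(cultures, function(g) {
    ref <- ko_peaks[ko_culture == g]
    if (length(ref) < 2) return(NA_real_)
    mean(ref) + n_sd * stats::sd(ref)
  }, 0)
  if (anyNA(thr))
    warning("culture(s) with < 2 knockout reference values: ",
            paste(cultures[is.na(thr)], collapse = ", "),
            " -> synapses flagged undetermined")
  threshold <- thr[match(culture, cultures)]
  positive <- ifelse(is.na(threshold), NA, peaks > threshold)
  calls <- data.frame(peak = peaks, culture = culture,
                      threshold = unname(threshold), positive = positive)
  det <- !is.na(positive)
  frac_by <- vapply(cultures, function(g) {
    p <- positive[culture == g]
    if (all(is.na(p))) NA_real_ else mean(p, na.rm = TRUE)
  }, 0)
  structure(
    list(calls = calls,
         thresholds = data.frame(culture = cultures, threshold = unname(thr),
                                 n_reference = vapply(cultures, function(g)
                                   sum(ko_culture == g), 0L)),
         fraction_positive = if (any(det)) mean(positive[det]) else NA_real_,
         fraction_by_culture = frac_by,
         n_undetermined = sum(!det),
         n_sd = n_sd),
    class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  cat(sprintf(
    "positivity_result: %.1f%% positive (%d/%d determined synapses; > mean + %g SD of KO reference per culture)\n",
    100 * x$fraction_positive,
    sum(x$calls$positive, na.rm = TRUE),
    sum(!is.na(x$calls$positive)), x$n_sd))
  if (x$n_undetermined > 0)
    cat("  undetermined:", x$n_undetermined, "\n")
  print(x$thresholds)
  invisible(x)
}
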