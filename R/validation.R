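#' Parameter-recovery studies against the synthetic generator
#'
#' Because the measurement chain can only be validated against known
#' ground truth, these studies render single-synapse scenes with random
#' orientation, sub-pixel placement and presynaptic side, run the full
#' profile chain (extraction, 5-pixel rolling average, windowed peak
#' search) with ROIs derived from the ground truth, and compare measured
#' peak-to-peak distances with the true offsets.
#'
#' `offset_recovery_study` scans a grid of fixed true offsets at high
#' signal-to-noise; `distribution_recovery_study` draws offsets from a
#' normal distribution (defaults 24 +/- 17 nm) and recovers its mean and
#' SD from the per-synapse measurements and the aligned average profile.
#'
#' @param offsets true offsets to scan, nm.
#' @param n_per_offset synapses per offset.
#' @param seed integer seed.
#' @param pixel_size_nm pixel pitch (default 20).
#' @param psf_fwhm_nm STED PSF FWHM (default 50).
#' @param amplitude peak photons for the scaffold/protein bands; the
#'   high default makes photon noise negligible relative to the signal.
#' @param noise noise model passed to the generator.
#' @param smooth_px,window_nm measurement-chain parameters.
#' @return `offset_recovery_study`: data frame (`true_offset_nm`,
#'   `measured_nm`) with a `mae_by_offset` attribute (mean absolute error
#'   per offset, nm).
#' @export
offset_recovery_study <- function(offsets = c(0, 20, 40, 60, 80),
                                  n_per_offset = 200, seed = 1,
                                  pixel_size_nm = 20, psf_fwhm_nm = 50,
                                  amplitude = 1000,
                                  noise = "poisson+gaussian",
                                  smooth_px = 5, window_nm = 100) {
  rows <- list()
  k <- 0
  for (off in offsets) {
    for (i in seq_len(n_per_offset)) {
      k <- k + 1
      m <- measure_single_synapse(off, seed + k, pixel_size_nm,
                                  psf_fwhm_nm, amplitude, noise,
                                  smooth_px, window_nm)
      rows[[k]] <- data.frame(true_offset_nm = off,
                              measured_nm = m$distance_nm)
    }
  }
  out <- do.call(rbind, rows)
  mae <- tapply(abs(out$measured_nm - out$true_offset_nm),
                out$true_offset_nm, mean)
  structure(out, mae_by_offset = mae)
}

#' @param n number of synapses for `distribution_recovery_study`.
#' @param offset_mean_nm,offset_sd_nm parameters of the sampled offset
#'   distribution.
#' @return `distribution_recovery_study`: a list with the per-synapse
#'   `measurements` data frame (`true_offset_nm`, `measured_nm`), the
#'   drawn-truth and measured unsigned mean/SD, and the protein-peak
#'   position of the aligned average profile.
#' @rdname offset_recovery_study
#' @export
distribution_recovery_study <- function(n = 50, offset_mean_nm = 24,
                                        offset_sd_nm = 17, seed = 1,
                                        pixel_size_nm = 20,
                                        psf_fwhm_nm = 50, amplitude = 100,
                                        noise = "poisson+gaussian",
                                        smooth_px = 5, window_nm = 100) {
  set.seed(seed)
  offs <- stats::rnorm(n, offset_mean_nm, offset_sd_nm)
  profiles <- list()
  rows <- list()
  for (i in seq_len(n)) {
    m <- measure_single_synapse(offs[i], seed + i, pixel_size_nm,
                                psf_fwhm_nm, amplitude, noise,
                                smooth_px, window_nm)
    rows[[i]] <- data.frame(true_offset_nm = offs[i],
                            measured_nm = m$distance_nm)
    profiles[[i]] <- m$profile
  }
  meas <- do.call(rbind, rows)
  avg <- align_and_average(profiles)
  pr <- avg[avg$channel == "protein", ]
  list(measurements = meas,
       truth_mean_unsigned = mean(abs(meas$true_offset_nm)),
       truth_sd_unsigned = stats::sd(abs(meas$true_offset_nm)),
       measured_mean_unsigned = mean(abs(meas$measured_nm)),
       measured_sd_unsigned = stats::sd(abs(meas$measured_nm)),
       average_profile = avg,
       average_profile_peak_nm = pr$position_nm[which.max(pr$mean)])
}

## one synapse, random pose, full truth-ROI measurement chain; returns the
## apposition measurement plus the smoothed profile
measure_single_synapse <- function(true_offset_nm, seed, pixel_size_nm,
                                   psf_fwhm_nm, amplitude, noise,
                                   smooth_px, window_nm) {
  set.seed(seed)
  size_px <- 96
  center <- (size_px - 1) * pixel_size_nm / 2 +
    stats::runif(2, -pixel_size_nm / 2, pixel_size_nm / 2)
  th <- stats::runif(1, 0, pi)
  syn <- synapse_truth(
    center_nm = center, orientation = c(cos(th), sin(th)),
    cloud_side = sample(c(-1L, 1L), 1), true_offset_nm = true_offset_nm,
    amplitudes = c(scaffold = amplitude * 1.2, protein = amplitude))
  chans <- list(channel_spec("scaffold", "sted", psf_fwhm_nm),
                channel_spec("protein", "sted", psf_fwhm_nm))
  sc <- render_scene(scene_spec(
    image_size_px = c(size_px, size_px), pixel_size_nm = pixel_size_nm,
    channels = chans, synapses = list(syn), noise = noise, seed = seed))
  roi <- roi_from_truth(sc$truth[1, ])
  prof <- smooth_profile(extract_profile(sc, roi), smooth_px)
  m <- measure_apposition(prof, window_nm = window_nm)
  m$profile <- prof
  m
}

#' Null calibration of the positivity rule
#'
#' Draws knockout-reference and test peak intensities from the same
#' Gaussian and classifies with the mean + 3 SD rule; under this null the
#' expected positive fraction is the standard-normal upper tail
#' P(Z > 3) = 0.135%.
#'
#' @param n_test,n_reference draw sizes.
#' @param mean,sd the common Gaussian.
#' @param seed integer seed.
#' @return list with `fraction_positive` and `expected` (0.00135).
#' @export
null_positivity_calibration <- function(n_test = 1e5, n_reference = 1e5,
                                        mean = 50, sd = 8, seed = 1) {
  set.seed(seed)
  ref <- stats::rnorm(n_reference, mean, sd)
  test <- stats::rnorm(n_test, mean, sd)
  res <- classify_positive(test, ko_peaks = ref)
  list(fraction_positive = res$fraction_positive,
       expected = stats::pnorm(3, lower.tail = FALSE))
}
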