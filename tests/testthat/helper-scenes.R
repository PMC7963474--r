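# shared fixtures: single-synapse scenes and independent oracles

# one synapse centered in a small field; center jitter in nm lets tests
# exercise sub-pixel placement
make_synapse_scene <- function(true_offset_nm = 0, orientation = c(1, 0),
                               cloud_side = 1, noise = "none", seed = 1,
                               pixel_size_nm = 20, size_px = 96,
                               amp = c(vesicle = 80, scaffold = 120,
                                       protein = 100),
                               center_jitter_nm = c(0, 0),
                               channels = default_channels(), ...) {
  center <- (size_px - 1) * pixel_size_nm / 2 + center_jitter_nm
  syn <- synapse_truth(center_nm = center, orientation = orientation,
                       cloud_side = cloud_side,
                       true_offset_nm = true_offset_nm,
                       amplitudes = amp, ...)
  render_scene(scene_spec(image_size_px = c(size_px, size_px),
                          pixel_size_nm = pixel_size_nm,
                          channels = channels,
                          synapses = list(syn), noise = noise,
                          seed = seed))
}

# truth-ROI measurement chain: extract -> smooth -> apposition
measure_scene_offset <- function(scene, smooth_px = 5, window_nm = 100,
                                 flip_normal = FALSE) {
  roi <- synappose:::roi_from_truth(scene$truth[1, ])
  if (flip_normal)
    roi <- sideview_roi(roi$bar_center_nm, -roi$axis_normal,
                        roi$profile_length_nm, roi$profile_width_nm)
  prof <- smooth_profile(extract_profile(scene, roi), smooth_px)
  measure_apposition(prof, window_nm = window_nm)
}

# exhaustive-search Otsu: maximize between-class variance over all 256
# histogram bin thresholds (independent of EBImage)
otsu_exhaustive <- function(image, levels = 256) {
  rng <- range(image)
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(as.vector(image), breaks = br, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  best <- -Inf; best_t <- mids[1]
  n <- sum(counts)
  for (k in seq_len(levels - 1)) {
    w0 <- sum(counts[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- br[k + 1] }
  }
  best_t
}

# rotate the whole image so direction dvec maps to +x (bilinear, onto a
# fine rotated raster deliberately offset from the profile sample points),
# then sample axis-aligned rows from the rotated raster: the independent
# cross-check for oblique extraction
rotate_then_sample_oracle <- function(img, pixel_size_nm, center_nm, dvec,
                                      length_nm, width_nm, fine = 4) {
  wvec <- synappose:::perp2(dvec)
  xg <- (seq_len(ncol(img)) - 1) * pixel_size_nm
  yg <- (seq_len(nrow(img)) - 1) * pixel_size_nm
  px <- pixel_size_nm / fine
  ## rotated raster grid (x' = along dvec, y' = along wvec), shifted by a
  ## fraction of a fine pixel so no sample point coincides with the grid
  tg <- seq(-length_nm / 2 - 2 * px, length_nm / 2 + 2 * px, by = px) +
    0.37 * px
  sg <- seq(-width_nm / 2 - 2 * px, width_nm / 2 + 2 * px, by = px) +
    0.37 * px
  ox <- center_nm[1] + outer(sg, tg, function(s, t) t * dvec[1] + s * wvec[1])
  oy <- center_nm[2] + outer(sg, tg, function(s, t) t * dvec[2] + s * wvec[2])
  rot <- matrix(pracma::interp2(xg, yg, img, as.vector(ox), as.vector(oy)),
                length(sg), length(tg))
  ## axis-aligned sampling of the rotated image at the profile grid
  tpos <- seq(-length_nm / 2, length_nm / 2, by = pixel_size_nm)
  spos <- seq(-width_nm / 2, width_nm / 2, by = pixel_size_nm)
  pts_t <- rep(tpos, times = length(spos))
  pts_s <- rep(spos, each = length(tpos))
  v <- pracma::interp2(tg, sg, rot, pts_t, pts_s)
  rowMeans(matrix(v, length(tpos), length(spos)))
}

# direct two-way ANOVA sum-of-squares decomposition (balanced designs),
# independent of stats::aov
anova_ss_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  grand <- mean(y)
  ssa <- sum(tapply(y, a, function(v) length(v) * (mean(v) - grand)^2))
  ssb <- sum(tapply(y, b, function(v) length(v) * (mean(v) - grand)^2))
  cellm <- tapply(y, list(a, b), mean)
  celln <- tapply(y, list(a, b), length)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  ssab <- sum(celln * (cellm - outer(am, rep(1, nlevels(b))) -
                         outer(rep(1, nlevels(a)), bm) + grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssa - ssb - ssab
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1
  dfab <- dfa * dfb
  dfe <- length(y) - nlevels(a) * nlevels(b)
  data.frame(term = c("a", "b", "ab"),
             F = c((ssa / dfa) / (sse / dfe),
                   (ssb / dfb) / (sse / dfe),
                   (ssab / dfab) / (sse / dfe)))
}

# bisection root-finder for level crossings of the closed-form IPSC
# waveform s(t) = A*norm*(exp(-t/td) - exp(-t/tr)), t from response onset
ipsc_crossing_oracle <- function(amplitude, tau_rise, tau_decay, level,
                                 lo, hi, tol = 1e-10) {
  pk <- synappose:::dexp_peak(tau_rise, tau_decay)
  f <- function(s) amplitude / pk$g *
    (exp(-s / tau_decay) - exp(-s / tau_rise)) - level
  stopifnot(sign(f(lo)) != sign(f(hi)))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
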