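## Separable Gaussian convolution with an explicitly normalized kernel and
## zero padding. The kernel is truncated at 4 sigma, so total counts are
## conserved up to boundary truncation (< 1% for sources >= ~5 FWHM from
## the image edge).
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- ceiling(4 * sigma_px)
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv_axis <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along_rows) nrow(m) else ncol(m)
    for (j in seq_along(k)) {
      s <- j - r - 1L   # shift in [-r, r]
      src <- seq_len(n) + s
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      if (along_rows)
        out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
      else
        out[, ok] <- out[, ok] + k[j] * m[, src[ok]]
    }
    out
  }
  conv_axis(conv_axis(mat, TRUE), FALSE)
}

## smoothed top-hat of full length L with Gaussian shoulders sigma_end,
## evaluated at along-axis coordinate a (closed form via erf)
soft_tophat <- function(a, length_nm, sigma_end = 20) {
  s <- sqrt(2) * sigma_end
  0.5 * (pracma::erf((length_nm / 2 - a) / s) +
         pracma::erf((length_nm / 2 + a) / s))
}

## expected photon field a single synapse adds to one channel, evaluated
## on the pixel grid restricted to a bounding window for speed
add_synapse_field <- function(field, syn, role, pixel_size) {
  amp <- unname(syn$amplitudes[role])
  if (is.na(amp)) amp <- 0
  if (amp <= 0) return(field)
  u <- syn$orientation
  nv <- perp2(u)                      # + normal; cloud on cloud_side * nv
  cx <- syn$center_nm[1]; cy <- syn$center_nm[2]
  reach <- syn$bar_length_nm / 2 + 3 * syn$cloud_radius_nm +
    abs(syn$true_offset_nm) + 8 * syn$bar_thickness_sigma_nm
  nr <- nrow(field); nc <- ncol(field)
  rows <- max(1, floor((cy - reach) / pixel_size) + 1):
          min(nr, ceiling((cy + reach) / pixel_size) + 1)
  cols <- max(1, floor((cx - reach) / pixel_size) + 1):
          min(nc, ceiling((cx + reach) / pixel_size) + 1)
  xs <- (cols - 1) * pixel_size - cx
  ys <- (rows - 1) * pixel_size - cy
  dx <- matrix(xs, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(ys, length(rows), length(cols))
  a <- dx * u[1] + dy * u[2]          # along the bar axis
  b <- dx * nv[1] + dy * nv[2]        # across it
  patch <- switch(role,
    scaffold = amp * soft_tophat(a, syn$bar_length_nm) *
      exp(-b^2 / (2 * syn$bar_thickness_sigma_nm^2)),
    protein = {
      d <- syn$true_offset_nm * syn$cloud_side
      amp * soft_tophat(a, syn$bar_length_nm) *
        exp(-(b - d)^2 / (2 * syn$bar_thickness_sigma_nm^2))
    },
    vesicle = {
      sc <- syn$cloud_radius_nm / 2
      bc <- b - syn$cloud_side * syn$cloud_radius_nm
      amp * exp(-(a^2 + bc^2) / (2 * sc^2))
    })
  field[rows, cols] <- field[rows, cols] + patch
  field
}

#' Render a synthetic multi-channel scene
#'
#' Evaluates the expected photon field of every synapse (scaffold bar with
#' Gaussian cross-section and soft top-hat ends; protein band displaced by
#' the true offset toward the presynaptic side; vesicle cloud as a Gaussian
#' blob), convolves each channel with its own normalized Gaussian PSF,
#' applies detector gain and background, and adds noise last
#' (Poisson photon noise, then additive Gaussian read noise).
#'
#' Synapses whose bar center lies closer than half a bar length to the
#' image border are dropped with a warning; the dropped rows are reported
#' in `attr(scene, "dropped")`.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `synthetic_scene`: a list with `channels`
#'   (named list of count matrices, rows = y, cols = x), `pixel_size_nm`,
#'   `channel_info` (data frame), `truth` (ground-truth data frame, one row
#'   per rendered synapse, coordinates in nm with the origin at the
#'   top-left pixel center) and the `spec` itself.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (length(spec$channels) == 0) stop("scene must have at least one channel")
  set.seed(spec$seed)
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  px <- spec$pixel_size_nm
  w_nm <- (nc - 1) * px; h_nm <- (nr - 1) * px

  margin <- function(s) s$bar_length_nm / 2
  inside <- vapply(spec$synapses, function(s) {
    m <- margin(s)
    s$center_nm[1] >= m && s$center_nm[1] <= w_nm - m &&
      s$center_nm[2] >= m && s$center_nm[2] <= h_nm - m
  }, TRUE)
  truth <- truth_table(spec$synapses)
  dropped <- truth[!inside, , drop = FALSE]
  if (nrow(dropped) > 0)
    warning(nrow(dropped), " synapse(s) outside image bounds were dropped")
  synapses <- spec$synapses[inside]
  truth <- truth[inside, , drop = FALSE]
  if (nrow(truth) > 0) truth$synapse <- seq_len(nrow(truth))

  ## distractors: round blobs, no bar/cloud pairing, split across channels
  distr <- list()
  if (spec$distractors > 0) {
    for (i in seq_len(spec$distractors)) {
      distr[[i]] <- list(
        x = stats::runif(1, 0.1 * w_nm, 0.9 * w_nm),
        y = stats::runif(1, 0.1 * h_nm, 0.9 * h_nm),
        sigma = stats::runif(1, 40, 80),
        amp = stats::runif(1, 30, 80),
        channel = sample(names(spec$channels), 1))
    }
  }

  channels <- lapply(spec$channels, function(ch) {
    field <- matrix(0, nr, nc)
    for (s in synapses) field <- add_synapse_field(field, s, ch$role, px)
    for (d in distr) if (d$channel == ch$marker) {
      rows <- max(1, floor((d$y - 4 * d$sigma) / px) + 1):
              min(nr, ceiling((d$y + 4 * d$sigma) / px) + 1)
      cols <- max(1, floor((d$x - 4 * d$sigma) / px) + 1):
              min(nc, ceiling((d$x + 4 * d$sigma) / px) + 1)
      dx <- matrix((cols - 1) * px - d$x, length(rows), length(cols),
                   byrow = TRUE)
      dy <- matrix((rows - 1) * px - d$y, length(rows), length(cols))
      field[rows, cols] <- field[rows, cols] +
        d$amp * exp(-(dx^2 + dy^2) / (2 * d$sigma^2))
    }
    blurred <- gaussian_blur(field, fwhm_to_sigma(ch$psf_fwhm_nm) / px)
    expected <- ch$background + ch$gain * blurred
    if (spec$noise == "none") return(expected)
    counts <- ch$gain *
      matrix(stats::rpois(nr * nc, pmax(expected, 0) / ch$gain), nr, nc)
    if (spec$noise == "poisson+gaussian" && spec$read_sigma > 0)
      counts <- counts + matrix(stats::rnorm(nr * nc, 0, spec$read_sigma),
                                nr, nc)
    counts
  })

  info <- data.frame(
    marker = names(spec$channels),
    modality = vapply(spec$channels, `[[`, "", "modality"),
    role = vapply(spec$channels, `[[`, "", "role"),
    psf_fwhm_nm = vapply(spec$channels, `[[`, 0, "psf_fwhm_nm"),
    background = vapply(spec$channels, `[[`, 0, "background"),
    gain = vapply(spec$channels, `[[`, 0, "gain"),
    row.names = NULL)

  structure(
    list(channels = channels, pixel_size_nm = px, channel_info = info,
         truth = truth, spec = spec),
    dropped = dropped, class = "synthetic_scene")
}

## ground-truth table, one row per synapse, flat columns
truth_table <- function(synapses) {
  if (length(synapses) == 0)
    return(data.frame(synapse = integer(), center_x_nm = numeric(),
                      center_y_nm = numeric(), orient_x = numeric(),
                      orient_y = numeric(), bar_length_nm = numeric(),
                      bar_thickness_sigma_nm = numeric(),
                      cloud_radius_nm = numeric(), cloud_side = integer(),
                      true_offset_nm = numeric()))
  rows <- lapply(seq_along(synapses), function(i) {
    s <- synapses[[i]]
    d <- data.frame(synapse = i,
                    center_x_nm = s$center_nm[1], center_y_nm = s$center_nm[2],
                    orient_x = s$orientation[1], orient_y = s$orientation[2],
                    bar_length_nm = s$bar_length_nm,
                    bar_thickness_sigma_nm = s$bar_thickness_sigma_nm,
                    cloud_radius_nm = s$cloud_radius_nm,
                    cloud_side = s$cloud_side,
                    true_offset_nm = s$true_offset_nm)
    for (nm in names(s$amplitudes))
      d[[paste0("amp_", nm)]] <- unname(s$amplitudes[nm])
    d
  })
  do.call(rbind, rows)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("synthetic_scene:", nrow(x$channels[[1]]), "x", ncol(x$channels[[1]]),
      "px @", x$pixel_size_nm, "nm/px\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  synapses:", nrow(x$truth), "rendered")
  nd <- nrow(attr(x, "dropped") %||% data.frame())
  if (nd > 0) cat(" (", nd, " dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a scene to disk (multi-page TIFF + ground-truth CSV)
#'
#' Channels are written as 32-bit float pages of a single TIFF in the order
#' of the scene spec, scaled into `[0, 1]` by a single per-scene factor
#' recorded in a JSON sidecar together with the pixel size and channel
#' table, so [read_scene()] restores counts exactly (up to float precision).
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param name basename for the three files.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lo <- min(0, vapply(scene$channels, min, 0))
  scale <- max(1, vapply(scene$channels, max, 0) - lo)
  pages <- lapply(scene$channels, function(m) (m - lo) / scale)
  tif <- file.path(dir, paste0(name, ".ome.tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(scene$truth, csv, row.names = FALSE)
  meta <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(
    list(pixel_size_nm = scene$pixel_size_nm, intensity_scale = scale,
         intensity_offset = lo, channel_info = scene$channel_info),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tif, truth = csv, meta = meta))
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory holding the files.
#' @param name basename used when writing.
#' @return a `synthetic_scene` (without the original `spec`).
#' @export
read_scene <- function(dir, name = "scene") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".ome.tif")),
                          all = TRUE)
  channels <- lapply(pages, function(p)
    p * meta$intensity_scale + (meta$intensity_offset %||% 0))
  names(channels) <- meta$channel_info$marker
  truth <- utils::read.csv(file.path(dir, paste0(name, "_truth.csv")))
  structure(
    list(channels = channels, pixel_size_nm = meta$pixel_size_nm,
         channel_info = as.data.frame(meta$channel_info), truth = truth,
         spec = NULL),
    class = "synthetic_scene")
}
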