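#' Imaging-channel specification
#'
#' Describes one acquisition channel of a synthetic scene: the marker it
#' carries, its modality (diffraction-limited confocal or superresolved
#' STED), the Gaussian point-spread-function width, and the detector model.
#'
#' @param marker text label for the stained protein, e.g. `"vesicle"`
#'   (Synaptophysin-like), `"scaffold"` (PSD-95/Gephyrin-like),
#'   `"protein"` (protein of interest).
#' @param modality `"confocal"` or `"sted"`.
#' @param psf_fwhm_nm full width at half maximum of the Gaussian PSF, nm.
#'   Defaults: 250 nm confocal, 50 nm STED.
#' @param background mean background counts per pixel (>= 0).
#' @param gain detector counts per photon.
#' @param role what the channel images at each synapse: the presynaptic
#'   `"vesicle"` cloud, the postsynaptic `"scaffold"` bar, or the displaced
#'   `"protein"` band. Defaults to `marker` when that is one of the three.
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(marker,
                         modality = c("sted", "confocal"),
                         psf_fwhm_nm = NULL,
                         background = 5,
                         gain = 1,
                         role = NULL) {
  modality <- match.arg(modality)
  if (is.null(psf_fwhm_nm))
    psf_fwhm_nm <- if (modality == "sted") 50 else 250
  if (is.null(role)) {
    if (!marker %in% c("vesicle", "scaffold", "protein"))
      stop("channel role cannot be inferred from marker '", marker,
           "'; give `role` explicitly")
    role <- marker
  }
  role <- match.arg(role, c("vesicle", "scaffold", "protein"))
  stopifnot(psf_fwhm_nm > 0, background >= 0, gain > 0)
  structure(
    list(marker = marker, modality = modality, psf_fwhm_nm = psf_fwhm_nm,
         background = background, gain = gain, role = role),
    class = "channel_spec")
}

#' Ground truth for one synthetic side-view synapse
#'
#' The geometry a side-view synapse contributes to a scene: a bar-like
#' postsynaptic scaffold (Gaussian cross-section along its normal, soft
#' top-hat along its long axis), a presynaptic vesicle cloud on one side,
#' and a protein band parallel to the bar, displaced by `true_offset_nm`
#' along the normal. Positive offsets point toward the presynaptic cloud.
#'
#' @param center_nm length-2 numeric, bar center (x, y) in nm; the origin
#'   is the center of the top-left pixel.
#' @param orientation unit vector of the bar's long axis (normalized here).
#' @param bar_length_nm full bar length, nm.
#' @param bar_thickness_sigma_nm Gaussian sigma of the bar (and of the
#'   protein band) across the normal, nm.
#' @param cloud_radius_nm vesicle-cloud radius, nm (Gaussian blob with
#'   sigma = radius/2, centered one radius away from the bar). The default
#'   500 nm emulates a bouton-sized Synaptophysin punctum (~1 um across,
#'   so it passes the 0.4-2 um^2 size filter after confocal blur).
#' @param cloud_side +1 or -1: on which side of the bar, along the +normal
#'   (the axis rotated +90 degrees), the presynaptic cloud sits.
#' @param true_offset_nm signed displacement of the protein band from the
#'   scaffold bar along the normal; positive = toward the presynaptic cloud.
#' @param amplitudes named numeric: peak photons per channel role,
#'   names among `vesicle`, `scaffold`, `protein`.
#' @return an object of class `synapse_truth`.
#' @export
synapse_truth <- function(center_nm,
                          orientation = c(1, 0),
                          bar_length_nm = 400,
                          bar_thickness_sigma_nm = 25,
                          cloud_radius_nm = 500,
                          cloud_side = 1,
                          true_offset_nm = 0,
                          amplitudes = c(vesicle = 80, scaffold = 120,
                                         protein = 100)) {
  stopifnot(length(center_nm) == 2, bar_length_nm > 0,
            bar_thickness_sigma_nm > 0, cloud_radius_nm > 0,
            cloud_side %in% c(-1, 1), is.numeric(amplitudes),
            !is.null(names(amplitudes)))
  structure(
    list(center_nm = as.numeric(center_nm),
         orientation = unit2(as.numeric(orientation)),
         bar_length_nm = bar_length_nm,
         bar_thickness_sigma_nm = bar_thickness_sigma_nm,
         cloud_radius_nm = cloud_radius_nm,
         cloud_side = as.integer(cloud_side),
         true_offset_nm = true_offset_nm,
         amplitudes = amplitudes),
    class = "synapse_truth")
}

#' Scene specification for the synthetic-image generator
#'
#' @param image_size_px integer length-2, image size (rows, cols) in pixels.
#' @param pixel_size_nm pixel pitch in nm (> 0). Default 20 nm, typical for
#'   STED acquisition and making a 5-pixel rolling average a 100 nm window.
#' @param channels list of [channel_spec()] objects (at least one).
#' @param synapses list of [synapse_truth()] objects.
#' @param distractors number of non-synaptic round blobs to scatter.
#' @param noise `"none"`, `"poisson"` or `"poisson+gaussian"`.
#' @param read_sigma Gaussian read-noise SD in counts (used for
#'   `"poisson+gaussian"`).
#' @param seed integer seed; a fixed seed makes [render_scene()] output
#'   byte-identical.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = c(96, 96),
                       pixel_size_nm = 20,
                       channels = default_channels(),
                       synapses = list(),
                       distractors = 0,
                       noise = c("poisson+gaussian", "poisson", "none"),
                       read_sigma = 2,
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(pixel_size_nm > 0, length(image_size_px) == 2,
            all(image_size_px >= 8), distractors >= 0, read_sigma >= 0)
  if (length(channels) == 0) stop("scene must have at least one channel")
  stopifnot(all(vapply(channels, inherits, TRUE, "channel_spec")))
  stopifnot(all(vapply(synapses, inherits, TRUE, "synapse_truth")))
  names(channels) <- vapply(channels, `[[`, "", "marker")
  if (anyDuplicated(names(channels))) stop("duplicate channel markers")
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_nm = pixel_size_nm,
         channels = channels, synapses = synapses,
         distractors = as.integer(distractors),
         noise = noise, read_sigma = read_sigma, seed = as.integer(seed)),
    class = "scene_spec")
}

#' Default three-channel layout: confocal vesicle marker plus STED
#' scaffold and protein-of-interest channels.
#' @export
default_channels <- function() {
  list(channel_spec("vesicle", "confocal"),
       channel_spec("scaffold", "sted"),
       channel_spec("protein", "sted"))
}

#' Read a scene specification from a YAML config
#'
#' The YAML mirrors the [scene_spec()] arguments; `channels` and `synapses`
#' are lists of argument maps passed to [channel_spec()] / [synapse_truth()].
#'
#' @param path YAML file path.
#' @return a `scene_spec`.
#' @export
scene_spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  chans <- lapply(y$channels, function(cc) do.call(channel_spec, cc))
  syns <- lapply(y$synapses, function(ss) {
    if (!is.null(ss$amplitudes)) ss$amplitudes <- unlist(ss$amplitudes)
    do.call(synapse_truth, ss)
  })
  scene_spec(image_size_px = unlist(y$image_size_px %||% c(96, 96)),
             pixel_size_nm = y$pixel_size_nm %||% 20,
             channels = chans, synapses = syns,
             distractors = y$distractors %||% 0,
             noise = y$noise %||% "poisson+gaussian",
             read_sigma = y$read_sigma %||% 2,
             seed = y$seed %||% 1L)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("scene_spec:", x$image_size_px[1], "x", x$image_size_px[2], "px @",
      x$pixel_size_nm, "nm/px;", length(x$channels), "channel(s) [",
      paste(names(x$channels), collapse = ", "), "];",
      length(x$synapses), "synapse(s);", x$distractors,
      "distractor(s); noise =", x$noise, "; seed =", x$seed, "\n")
  invisible(x)
}
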