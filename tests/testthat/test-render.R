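test_that("ground-truth table has one row per rendered synapse", {
  syns <- lapply(1:10, function(i)
    synapse_truth(center_nm = c(700 + 850 * ((i - 1) %% 4),
                                700 + 850 * ((i - 1) %/% 4)),
                  true_offset_nm = 10 * i))
  sc <- render_scene(scene_spec(image_size_px = c(220, 220),
                                synapses = syns, noise = "none"))
  expect_equal(nrow(sc$truth), 10)
  expect_equal(sc$truth$true_offset_nm, 10 * (1:10))
  expect_equal(names(sc$channels), c("vesicle", "scaffold", "protein"))
})

test_that("normalized PSF kernel conserves counts away from boundaries", {
  m <- matrix(0, 64, 64); m[32, 33] <- 7; m[30, 28] <- 3
  for (sigma in c(1, 2.5, 5))
    expect_equal(sum(synappose:::gaussian_blur(m, sigma)), sum(m),
                 tolerance = 1e-9)
  ## scene-level: interior synapse, blur changes total counts < 1%
  chan_narrow <- list(channel_spec("scaffold", "sted", psf_fwhm_nm = 1,
                                   background = 0))
  chan_sted <- list(channel_spec("scaffold", "sted", psf_fwhm_nm = 50,
                                 background = 0))
  syn <- list(synapse_truth(c(1270, 1270)))
  sp <- function(ch) scene_spec(image_size_px = c(128, 128), channels = ch,
                                synapses = syn, noise = "none")
  s1 <- sum(render_scene(sp(chan_narrow))$channels$scaffold)
  s2 <- sum(render_scene(sp(chan_sted))$channels$scaffold)
  expect_lt(abs(s1 - s2) / s1, 0.01)
})

test_that("rendering is deterministic for a fixed seed", {
  sp <- scene_spec(synapses = list(synapse_truth(c(950, 950))),
                   distractors = 3, noise = "poisson+gaussian", seed = 42)
  a <- render_scene(sp); b <- render_scene(sp)
  expect_identical(a$channels, b$channels)
})

test_that("out-of-bounds synapses are dropped and reported", {
  syns <- list(synapse_truth(c(950, 950)), synapse_truth(c(30, 950)))
  expect_warning(
    sc <- render_scene(scene_spec(synapses = syns, noise = "none")),
    "dropped")
  expect_equal(nrow(sc$truth), 1)
  expect_equal(nrow(attr(sc, "dropped")), 1)
})

test_that("a scene must have at least one channel", {
  expect_error(scene_spec(channels = list()), "at least one channel")
})

test_that("knockout-style protein amplitude 0 leaves background only", {
  sc <- make_synapse_scene(true_offset_nm = 30,
                           amp = c(vesicle = 80, scaffold = 120,
                                   protein = 0))
  bg <- sc$channel_info$background[sc$channel_info$marker == "protein"]
  expect_equal(max(abs(sc$channels$protein - bg)), 0)
  ## scaffold channel unaffected
  expect_gt(max(sc$channels$scaffold), bg + 50)
})

test_that("protein peak intensity increases strictly with amplitude", {
  peaks <- vapply(c(50, 100, 150), function(a) {
    sc <- make_synapse_scene(true_offset_nm = 20,
                             amp = c(vesicle = 80, scaffold = 120,
                                     protein = a))
    measure_scene_offset(sc)$protein_peak_intensity
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("positive offsets bias the average profile toward the presynapse", {
  profs <- lapply(1:6, function(i) {
    sc <- make_synapse_scene(true_offset_nm = 40,
                             orientation = c(cos(i), sin(i)),
                             cloud_side = c(-1, 1)[i %% 2 + 1],
                             center_jitter_nm = c(7 * i %% 20, 11 * i %% 20))
    roi <- synappose:::roi_from_truth(sc$truth[1, ])
    smooth_profile(extract_profile(sc, roi), 5)
  })
  avg <- align_and_average(profs)
  pr <- avg[avg$channel == "protein", ]
  bg <- 5
  pre <- sum(pr$mean[pr$position_nm > 0] - bg)
  post <- sum(pr$mean[pr$position_nm < 0] - bg)
  expect_gt(pre, post)
})

test_that("scene IO round-trips through TIFF + sidecars", {
  sc <- make_synapse_scene(true_offset_nm = 24, noise = "poisson+gaussian",
                           seed = 5)
  d <- withr::local_tempdir()
  write_scene(sc, d, "s1")
  back <- read_scene(d, "s1")
  expect_equal(back$pixel_size_nm, sc$pixel_size_nm)
  expect_equal(back$channels$protein, sc$channels$protein,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$truth$true_offset_nm, sc$truth$true_offset_nm)
})
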