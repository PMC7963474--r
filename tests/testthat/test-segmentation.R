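test_that("Otsu threshold matches the exhaustive-search oracle", {
  set.seed(7)
  img <- matrix(10 + rnorm(4000, sd = 1), 50, 80)
  obj <- cbind(sample(10:40, 300, TRUE), sample(10:70, 300, TRUE))
  img[obj] <- 100 + rnorm(300, sd = 2)
  mask <- auto_threshold(img, "otsu")
  t_oracle <- otsu_exhaustive(img)
  expect_equal(mask, img > t_oracle, ignore_attr = TRUE)
  ## and the mask is exactly the bright mode
  expect_equal(mask, img > 50, ignore_attr = TRUE)
})

test_that("constant and all-zero images give an empty mask, not an error", {
  expect_warning(m <- auto_threshold(matrix(0, 10, 10)), "constant")
  expect_false(any(m))
  expect_warning(m2 <- auto_threshold(matrix(3.7, 5, 5), "isodata"))
  expect_false(any(m2))
})

test_that("isodata converges to the intermeans fixed point", {
  set.seed(1)
  x <- matrix(c(rnorm(500, 10, 1), rnorm(500, 100, 5)), 20, 50)
  m <- auto_threshold(x, "isodata")
  t <- attr(m, "threshold")
  expect_equal(t, (mean(x[x <= t]) + mean(x[x > t])) / 2, tolerance = 1e-4)
})

test_that("labeling agrees with EBImage on 4-connectivity and merges diagonals at 8", {
  set.seed(11)
  for (i in 1:5) {
    mask <- matrix(runif(900) < 0.35, 30, 30)
    mine <- label_components(mask, 4)
    ref <- EBImage::bwlabel(mask)
    expect_equal(max(mine), max(ref))
    ## identical partitions up to renumbering
    tab <- table(mine[mask], ref[mask])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  diagonal <- matrix(FALSE, 5, 5); diag(diagonal) <- TRUE
  expect_equal(max(label_components(diagonal, 4)), 5)
  expect_equal(max(label_components(diagonal, 8)), 1)
})

test_that("size filter retains exactly the components within 0.4-2 um^2", {
  ## 20 nm pixels: 0.2 um^2 = 500 px, 0.5 um^2 = 1250 px, 2.5 um^2 = 6250 px
  img <- matrix(0, 220, 220)
  img[10 + 1:20, 10 + 1:25] <- 100       # 500 px
  img[60 + 1:25, 60 + 1:50] <- 100       # 1250 px
  img[120 + 1:63, 110 + 1:100] <- 100    # 6300 px (> 2 um^2)
  p <- segmentation_params("fixed", threshold_value = 50)
  tab <- detect_puncta(img, p, 20)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$area_um2, 0.5)
  ## inclusive bounds: exactly 0.4 um^2 (1000 px) and 2.0 um^2 (5000 px)
  img2 <- matrix(0, 220, 220)
  img2[10 + 1:25, 10 + 1:40] <- 100      # 1000 px = 0.4 um^2
  img2[100 + 1:50, 100 + 1:100] <- 100   # 5000 px = 2.0 um^2
  tab2 <- detect_puncta(img2, p, 20)
  expect_equal(sort(tab2$area_um2), c(0.4, 2.0))
})

test_that("retained set equals brute-force enumeration on random blob images", {
  set.seed(23)
  p <- segmentation_params("fixed", connectivity = 4,
                           threshold_value = 0.5)
  for (rep in 1:5) {
    img <- matrix(0, 80, 80)
    for (b in 1:6) {
      r0 <- sample(5:60, 1); c0 <- sample(5:60, 1)
      h <- sample(3:18, 1); w <- sample(3:18, 1)
      img[r0:min(80, r0 + h), c0:min(80, c0 + w)] <- 1
    }
    tab <- detect_puncta(img, p, 100)    # 100 nm px: 1 px = 0.01 um^2
    ## oracle: EBImage 4-connectivity labeling + integer pixel counting
    ref <- EBImage::bwlabel(img > 0.5)
    n_px <- as.vector(table(ref[ref > 0]))
    keep <- sort(n_px[n_px >= 40 & n_px <= 200])   # 0.4 and 2 um^2
    expect_equal(sort(round(tab$area_um2 / 0.01)), keep)
  }
})

test_that("empty masks give a zero-count table with missing means", {
  expect_warning(tab <- detect_puncta(matrix(1, 50, 50),
                                      segmentation_params(), 20))
  s <- attr(tab, "summary")
  expect_equal(s$count, 0)
  expect_equal(s$density_per_100um2, 0)
  expect_true(is.na(s$mean_area_um2) && is.na(s$mean_intensity))
})

test_that("density is field-area normalized: 2x2 tiling preserves it", {
  img <- matrix(0, 110, 110)
  img[20 + 1:30, 20 + 1:40] <- 100
  img[70 + 1:25, 60 + 1:45] <- 100
  tiled <- rbind(cbind(img, img), cbind(img, img))
  p <- segmentation_params("fixed", threshold_value = 50)
  t1 <- detect_puncta(img, p, 20)
  t4 <- detect_puncta(tiled, p, 20)
  expect_equal(attr(t4, "summary")$count, 4 * attr(t1, "summary")$count)
  expect_equal(attr(t4, "summary")$density_per_100um2,
               attr(t1, "summary")$density_per_100um2, tolerance = 1e-12)
})

test_that("pixel size is mandatory for area conversion", {
  expect_error(detect_puncta(matrix(1:9, 3, 3), segmentation_params()),
               "pixel_size_nm")
})

test_that("segmentation recovers the true punctum count at >= 3 FWHM spacing", {
  syns <- lapply(list(c(1200, 1200), c(2700, 1300), c(1400, 2700)),
                 function(ctr) synapse_truth(ctr, orientation = c(0, 1)))
  sc <- render_scene(scene_spec(image_size_px = c(200, 200),
                                synapses = syns, noise = "none"))
  tab <- detect_puncta(sc$channels$vesicle, segmentation_params(), 20)
  expect_equal(attr(tab, "summary")$count, 3)
})

test_that("mask-level measurement averages only inside the mask", {
  img <- matrix(10, 20, 20); img[5:10, 5:10] <- 100
  full <- matrix(TRUE, 20, 20)
  expect_equal(measure_within_mask(img, full), mean(img))
  expect_equal(measure_within_mask(matrix(7, 8, 8), matrix(c(TRUE, FALSE), 8, 8)), 7)
  bright <- img > 50
  expect_equal(measure_within_mask(img, bright), 100)
  expect_warning(v <- measure_within_mask(img, matrix(FALSE, 20, 20)))
  expect_true(is.na(v))
})
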