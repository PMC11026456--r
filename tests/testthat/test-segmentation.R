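# Segmentation and intensity quantification.

make_scene <- function(noise_sd = 0, seed = 1) {
  gen_cell_scene(list(
    scene_object("disk", c(40, 40), radius_um = 8,
                 intensity = c(actin = 100, yap = 60),
                 nucleus = scene_object("disk", c(40, 40), radius_um = 3,
                                        class = "nucleus",
                                        intensity = c(actin = 150, yap = 120))),
    scene_object("disk", c(90, 90), radius_um = 10,
                 intensity = c(actin = 120, yap = 60))),
    size_px = 256, pixel_size = 0.5, background = 10,
    noise_sd = noise_sd, seed = seed)
}

test_that("segment_objects finds synthetic disks with accurate areas", {
  sc <- make_scene(noise_sd = 18, seed = 4)  # SNR = 90/18 = 5
  m <- segment_objects(sc$channels$actin)
  expect_equal(n_objects(m), 2L)
  areas <- sort(tabulate(m[m > 0]) * attr(m, "pixel_size")^2)
  truth <- sort(sc$truth$objects$area_um2[sc$truth$objects$class == "cell"])
  expect_true(all(abs(areas - truth) / truth < 0.02))
  # blank image: empty mask with a warning, not an error
  blank <- raster_image(matrix(5, 64, 64), 0.5)
  expect_warning(mb <- segment_objects(blank), "blank")
  expect_equal(n_objects(mb), 0L)
  # numeric global threshold path
  m2 <- segment_objects(sc$channels$actin, method = 50)
  expect_equal(n_objects(m2), 2L)
})

test_that("adaptive thresholding handles an intensity gradient", {
  px <- 0.5
  grad <- matrix(rep(seq(0, 60, length.out = 128), each = 128), 128, 128)
  img <- grad
  img[40:60, 40:60] <- img[40:60, 40:60] + 80
  # threshold = local mean - offset; a negative offset demands pixels to
  # exceed the local mean, suppressing the smooth gradient background
  m <- segment_objects(raster_image(img, px), method = "adaptive",
                       adaptive_block = 31, adaptive_offset = -20)
  expect_equal(n_objects(m), 1L)
  expect_equal(sum(m != 0), 21 * 21, tolerance = 0.1)
})

test_that("cytoplasm_mask is the set difference cell minus nucleus", {
  sc <- make_scene()
  cell <- sc$truth$masks$cell
  nuc <- sc$truth$masks$nucleus
  cyto <- cytoplasm_mask(cell, nuc)
  expect_equal(sum(cyto == 1), sum(cell == 1) - sum(nuc == 1))
  # empty nucleus mask: cytoplasm equals cell
  empty <- label_mask(matrix(0L, nrow(cell), ncol(cell)), 0.5)
  expect_equal(unclass(cytoplasm_mask(cell, empty))[, ], unclass(cell)[, ])
  # nucleus = cell: empty cytoplasm, flagged
  degen <- cytoplasm_mask(cell, cell)
  expect_equal(sum(degen != 0), 0)
  expect_true(all(c(1, 2) %in% attr(degen, "empty_labels")))
  expect_error(cytoplasm_mask(cell, label_mask(matrix(0L, 4, 4), 0.5)),
               "shapes differ")
})

test_that("mean_intensity subtracts background and recovers truth", {
  img <- raster_image(matrix(50, 32, 32), 1)
  msk <- label_mask(matrix(as.integer(matrix(seq_len(32^2) %in% 1:64, 32)), 32), 1)
  res <- mean_intensity(img, msk, background = 10)
  expect_equal(res$background_subtracted_mean, 40)
  expect_error(mean_intensity(img, msk, labels = 5), "absent")
  # noisy scene: recovered means within noise-predicted tolerance (5 sigma)
  sc <- gen_cell_scene(list(
    scene_object("disk", c(40, 40), radius_um = 8, intensity = c(td = 100)),
    scene_object("disk", c(90, 90), radius_um = 10, intensity = c(td = 120))),
    size_px = 256, pixel_size = 0.5, background = 10, noise_sd = 5, seed = 2)
  m <- sc$truth$masks$cell
  res <- mean_intensity(sc$channels$td, m, background = 10)
  n_px <- sc$truth$objects$area_px
  expect_true(all(abs(res$background_subtracted_mean - c(90, 110)) <
                    5 * 5 / sqrt(n_px)))
  # negative subtracted means clamp with warning
  expect_warning(r2 <- mean_intensity(sc$channels$td, m, background = 1000),
                 "clamped")
  expect_true(all(r2$background_subtracted_mean == 0))
})

test_that("yap_ratio: unity, exact factor two, scale invariance", {
  sc <- make_scene()
  nuc <- sc$truth$masks$nucleus
  cyto <- cytoplasm_mask(sc$truth$masks$cell, nuc)
  uni <- raster_image(matrix(33, 256, 256), 0.5)
  expect_equal(yap_ratio(uni, nuc, cyto)$ratio, 1)
  r <- yap_ratio(sc$channels$yap, nuc, cyto)
  expect_equal(r$ratio[r$object_id == 1], 2)
  scaled <- raster_image(unclass(sc$channels$yap) * 3.7, 0.5)
  expect_equal(yap_ratio(scaled, nuc, cyto)$ratio, r$ratio, tolerance = 1e-12)
  # zero cytoplasmic mean -> NA with warning
  zero <- raster_image(matrix(0, 256, 256), 0.5)
  expect_warning(rz <- yap_ratio(zero, nuc, cyto), "zero cytoplasmic")
  expect_true(all(is.na(rz$ratio)))
})

test_that("plane_intensity_profile averages selected planes over the mask", {
  arr <- array(0, c(16, 16, 4))
  for (k in 1:4) arr[, , k] <- k * 10
  st <- image_stack(arr, pixel_size = 1, z_step = 5)
  full <- matrix(TRUE, 16, 16)
  expect_equal(plane_intensity_profile(st, full, c(0, 5, 10, 15)), 25)
  # single-plane request equals that plane's mean
  expect_equal(plane_intensity_profile(st, full, 5), 20)
  # half mask of a uniform stack gives the same result as the full mask
  half <- matrix(FALSE, 16, 16); half[, 1:8] <- TRUE
  expect_equal(plane_intensity_profile(st, half, c(0, 5, 10, 15)), 25)
  expect_error(plane_intensity_profile(st, full, 40), "beyond stack range")
})
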