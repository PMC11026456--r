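# PIV displacement recovery and FTTC inversion.

test_that("piv_displacement: zero field and exact rigid shift", {
  sub <- substrate_model(3000, 0.5, 1)
  pair <- gen_bead_image_pair(NULL, sub, size_px = 128, noise_sd = 0, seed = 2,
                              override_shift_um = c(0, 0))
  u0 <- piv_displacement(pair$reference, pair$reference, piv_params())
  expect_lt(max(abs(c(u0$vx, u0$vy))), 1e-9)
  # integer 3 px x-shift: unbiased and recovered at every node (exactness
  # holds only for periodic images; finite windows leave boundary-term
  # jitter on individual vectors)
  ps <- gen_bead_image_pair(NULL, sub, size_px = 128, noise_sd = 0, seed = 2,
                            override_shift_um = c(3, 0))
  us <- piv_displacement(ps$reference, ps$deformed, piv_params())
  expect_lt(abs(mean(us$vx) - 3), 0.02)
  expect_lt(abs(mean(us$vy)), 0.02)
  expect_lt(max(abs(us$vx - 3)), 0.3)
  expect_error(piv_displacement(
    raster_image(matrix(1, 16, 16), 1), raster_image(matrix(1, 16, 16), 1),
    piv_params()), "blank|smaller")
})

test_that("piv_displacement grid geometry and parameter validation", {
  expect_error(piv_params(window = 4), "window")
  expect_error(piv_params(overlap = 1), "overlap")
  sub <- substrate_model(3000, 0.5, 0.65)
  p <- gen_bead_image_pair(NULL, sub, size_px = 96, noise_sd = 0, seed = 5,
                           override_shift_um = c(0.5, 0))
  u <- piv_displacement(p$reference, p$deformed, piv_params(window = 32))
  # nodes at window centers, spacing window*(1-overlap) px
  expect_equal(u$spacing, 16 * 0.65)
  expect_equal(dim(u$vx), c(5, 5))
  expect_equal(u$origin, c(15.5 * 0.65, 15.5 * 0.65))
})

test_that("fttc_tractions: zero input, linearity, validation", {
  sub <- substrate_model(3000, 0.5, 1)
  z <- vector_field(matrix(0, 16, 16), matrix(0, 16, 16), 8, units = "um")
  expect_equal(max(abs(fttc_tractions(z, sub)$vx)), 0)
  tr <- traction_field_from_spec(balanced_patch_pair(c(64, 64), 40, 100, 12),
                                 32, 4)
  u <- forward_displacement(tr, sub)
  t1 <- fttc_tractions(u, sub)
  u2 <- vector_field(2 * u$vx, 2 * u$vy, u$spacing, units = "um")
  t2 <- fttc_tractions(u2, sub)
  expect_equal(t2$vx, 2 * t1$vx, tolerance = 1e-10)
  expect_error(fttc_tractions(u, sub, lambda = -1), "lambda")
  uu <- u; uu$vx[1, 1] <- NaN
  expect_error(fttc_tractions(uu, sub), "non-finite")
})

test_that("fttc round trip on an exact fine grid stays under 15%", {
  sub <- substrate_model(3000, 0.5, 1)
  tr <- traction_field_from_spec(
    balanced_patch_pair(c(128, 128), 100, 150, 25), 256, 1)
  u <- forward_displacement(tr, sub, "spectral")
  trec <- fttc_tractions(u, sub, lambda = 1e-9 * 3000)
  mag <- sqrt(tr$vx^2 + tr$vy^2)
  sup <- mag > 0.1 * max(mag)
  err <- sqrt(mean((trec$vx[sup] - tr$vx[sup])^2 +
                   (trec$vy[sup] - tr$vy[sup])^2)) / sqrt(mean(mag[sup]^2))
  expect_lt(err, 0.15)
})

test_that("fttc is equivariant under 90-degree field rotations", {
  sub <- substrate_model(3000, 0.5, 1)
  tr <- traction_field_from_spec(
    balanced_patch_pair(c(60, 70), 40, 120, 12, orientation = 30), 32, 4)
  u <- forward_displacement(tr, sub, pad = FALSE)
  t_plain <- fttc_tractions(u, sub, pad = FALSE)
  t_rot <- fttc_tractions(rot_field_90(u), sub, pad = FALSE)
  expect_equal(rot_field_90(t_plain)$vx, t_rot$vx,
               tolerance = 1e-6 * max(abs(t_plain$vx)))
  expect_equal(rot_field_90(t_plain)$vy, t_rot$vy,
               tolerance = 1e-6 * max(abs(t_plain$vx)))
})

test_that("displacement gaps are filled before inversion", {
  sub <- substrate_model(3000, 0.5, 1)
  tr <- traction_field_from_spec(balanced_patch_pair(c(64, 64), 40, 100, 12),
                                 32, 4)
  u <- forward_displacement(tr, sub)
  ug <- u
  ug$valid[10, 10] <- FALSE
  ug$vx[10, 10] <- 1e6  # garbage behind an invalid flag
  t_ref <- fttc_tractions(u, sub)
  t_gap <- fttc_tractions(ug, sub)
  expect_lt(max(abs(t_gap$vx - t_ref$vx)) / max(abs(t_ref$vx)), 0.1)
})

test_that("mean_traction averages |T| over the masked nodes", {
  v <- vector_field(matrix(30, 8, 8), matrix(40, 8, 8), 4, units = "Pa")
  expect_equal(mean_traction(v), 50)
  half <- matrix(FALSE, 8, 8); half[, 1:4] <- TRUE
  expect_equal(mean_traction(v, half), 50)
  # mask covering only the zero half of a two-valued field
  v2 <- v; v2$vx[, 1:4] <- 0; v2$vy[, 1:4] <- 0
  expect_equal(mean_traction(v2, half), 0)
  expect_error(mean_traction(v, matrix(FALSE, 8, 8)), "overlap")
  # brute-force oracle on a synthetic patch field with a pixel-raster mask
  tr <- traction_field_from_spec(balanced_patch_pair(c(64, 64), 40, 100, 12),
                                 32, 4)
  px_mask <- matrix(0L, 128, 128)
  px_mask[33:96, 33:96] <- 1L
  msk <- label_mask(px_mask, pixel_size = 1)
  co <- field_coords(tr)
  inside <- co$x >= 32 & co$x <= 95 & co$y >= 32 & co$y <= 95
  oracle <- mean(sqrt(tr$vx[inside]^2 + tr$vy[inside]^2))
  expect_equal(mean_traction(tr, msk), oracle, tolerance = 1e-12)
})
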