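# Generators: forward elasticity, bead pairs, scenes, stacks, contours,
# tracks, expression.

test_that("forward_displacement is linear and scales as 1/E", {
  sub <- substrate_model(3000, 0.5, 1)
  t1 <- traction_field_from_spec(balanced_patch_pair(c(32, 32), 20, 100, 6),
                                 32, 2)
  t2 <- traction_field_from_spec(balanced_patch_pair(c(40, 30), 24, 80, 8, 90),
                                 32, 2)
  u1 <- forward_displacement(t1, sub)
  u2 <- forward_displacement(t2, sub)
  tsum <- vector_field(2 * t1$vx + 3 * t2$vx, 2 * t1$vy + 3 * t2$vy,
                       t1$spacing, units = "Pa")
  usum <- forward_displacement(tsum, sub)
  expect_lt(max(abs(usum$vx - (2 * u1$vx + 3 * u2$vx))),
            1e-8 * max(abs(usum$vx)))
  # zero traction -> zero displacement
  tz <- vector_field(matrix(0, 16, 16), matrix(0, 16, 16), 2, units = "Pa")
  expect_equal(max(abs(forward_displacement(tz, sub)$vx)), 0)
  # doubling E halves u pointwise
  u_half <- forward_displacement(t1, substrate_model(6000, 0.5, 1))
  expect_equal(2 * u_half$vx, u1$vx, tolerance = 1e-12)
  expect_error(substrate_model(-1), "youngs_modulus")
  expect_error(forward_displacement(
    vector_field(matrix(0, 1, 5), matrix(0, 1, 5), 1, units = "Pa"), sub),
    "2 points")
})

test_that("spectral and direct-summation forward solutions agree", {
  sub <- substrate_model(3000, 0.5, 1)
  tr <- traction_field_from_spec(
    balanced_patch_pair(c(128, 128), 60, 150, 15), 128, 2)
  expect_lt(max(abs(net_force(tr))), 1e-6 * sum(abs(tr$vx)))
  u_sp <- forward_displacement(tr, sub, "spectral")
  u_ds <- forward_displacement(tr, sub, "direct_sum", support_tol = 1e-9)
  i <- 17:112  # interior
  expect_lt(rel_rms(cbind(u_sp$vx[i, i], u_sp$vy[i, i]),
                    cbind(u_ds$vx[i, i], u_ds$vy[i, i])), 0.05)
})

test_that("gen_bead_image_pair: determinism, zero traction, rigid shift", {
  sub <- substrate_model(3000, 0.5, 1)
  spec <- balanced_patch_pair(c(64, 64), 40, 100, 10)
  p1 <- gen_bead_image_pair(spec, sub, size_px = 128, seed = 11)
  p2 <- gen_bead_image_pair(spec, sub, size_px = 128, seed = 11)
  expect_identical(unclass(p1$reference), unclass(p2$reference))
  expect_identical(unclass(p1$deformed), unclass(p2$deformed))
  # zero traction: reference and deformed identical
  z <- traction_spec(list(list(center = c(64, 64), peak = 0, width = 10,
                               orientation = 0, anisotropy = 1)))
  pz <- gen_bead_image_pair(z, sub, size_px = 128, noise_sd = 0, seed = 3)
  expect_equal(unclass(pz$reference), unclass(pz$deformed), tolerance = 1e-12)
  # rigid 3 px shift moves beads exactly 3 px
  ps <- gen_bead_image_pair(NULL, sub, size_px = 128, noise_sd = 0, seed = 3,
                            override_shift_um = c(3, 0))
  expect_equal(ps$truth$bead_positions_deformed[, 1],
               ps$truth$bead_positions[, 1] + 3)
  expect_error(gen_bead_image_pair(spec, sub, noise_sd = -1), "noise_sd")
})

test_that("gen_cell_scene: masks, intensities, disjointness", {
  sc <- gen_cell_scene(list(
    scene_object("disk", c(30, 30), radius_um = 10,
                 intensity = c(gray = 100))),
    size_px = 128, pixel_size = 0.5, background = 10, seed = 1)
  m <- sc$truth$masks$cell
  expect_equal(sum(sc$channels$gray == 100), sum(m == 1))
  expect_equal(sc$truth$objects$area_px, sum(m == 1))
  # empty spec -> uniform background, empty masks
  sc0 <- gen_cell_scene(list(), size_px = 32, background = 7, seed = 1)
  expect_true(all(sc0$channels[[1]] == 7))
  expect_equal(max(sc0$truth$masks$cell), 0L)
  # nucleus at 2x cytoplasm intensity -> ratio ground truth 2
  sc2 <- gen_cell_scene(list(
    scene_object("disk", c(30, 30), radius_um = 10, intensity = c(yap = 50),
                 nucleus = scene_object("disk", c(30, 30), radius_um = 4,
                                        class = "nucleus",
                                        intensity = c(yap = 100)))),
    size_px = 128, pixel_size = 0.5, seed = 1)
  obj <- sc2$truth$objects
  expect_equal(obj$yap[obj$class == "nucleus"] / obj$yap[obj$class == "cell"], 2)
  # overlapping same-class objects are rejected
  expect_error(gen_cell_scene(list(
    scene_object("disk", c(30, 30), radius_um = 10, intensity = c(g = 1)),
    scene_object("disk", c(33, 30), radius_um = 10, intensity = c(g = 1))),
    size_px = 128, pixel_size = 0.5), "overlap")
})

test_that("gen_cluster_stack ground truth follows cap geometry", {
  st <- gen_cluster_stack(10, 10, z_step = 0.5, pixel_size = 0.5)
  expect_equal(st$truth$angle_deg, 90)
  st2 <- gen_cluster_stack(4, 2, z_step = 0.25, pixel_size = 0.25)
  expect_equal(st2$truth$R_sphere, 5)
  # basal slice disk radius equals R within one pixel
  basal <- st$stack[, , 1] > 50
  r_meas <- sqrt(sum(basal) * attr(st$stack, "pixel_size")^2 / pi)
  expect_lt(abs(r_meas - 10), attr(st$stack, "pixel_size"))
  # truth angle matches the analytic cap angle to < 0.1 degree
  for (g in list(c(10, 4), c(6, 9), c(5, 5))) {
    s <- gen_cluster_stack(g[1], g[2], z_step = 0.5)
    rs <- (g[1]^2 + g[2]^2) / (2 * g[2])
    ana <- asin(min(g[1] / rs, 1)) * 180 / pi
    if (g[2] > rs) ana <- 180 - ana
    expect_lt(abs(s$truth$angle_deg - ana), 0.1)
  }
})

test_that("gen_contours families and truth", {
  expect_error(gen_contours(0), "n must be")
  circ <- gen_contours(8, "circle", seed = 1)
  expect_true(all(abs(circ$truth$porosity - 1) < 1e-6))
  notch <- gen_contours(8, "notched", seed = 1)
  expect_true(all(notch$truth$porosity > 1))
  # analytic circle area matches dense truth
  expect_equal(circ$truth$area_um2,
               vapply(circ$contours, contour_area, numeric(1)),
               tolerance = 1e-3)
})

test_that("gen_tracks closed-form velocities and determinism", {
  s <- gen_tracks(3, "stationary", n_frames = 5, seed = 1)
  expect_true(all(s$truth$velocity_um_min == 0))
  l <- gen_tracks(2, "linear", step = 5, n_frames = 10, frame_interval = 20,
                  seed = 2)
  expect_equal(l$truth$velocity_um_min, rep(45 / 180, 2))
  expect_identical(gen_tracks(4, "random_walk", seed = 9)$centroids,
                   gen_tracks(4, "random_walk", seed = 9)$centroids)
  expect_error(gen_tracks(2, n_frames = 1), "n_frames")
  expect_error(gen_tracks(2, step = -1), "step")
})

test_that("gen_expression planting, determinism and noiseless separation", {
  e1 <- gen_expression(n_cells = 100, n_genes = 20, seed = 5)
  e2 <- gen_expression(n_cells = 100, n_genes = 20, seed = 5)
  expect_identical(unclass(e1), unclass(e2))
  expect_true(all(e1 >= 0))
  expect_error(gen_expression(n_genes = 5), "n_genes")
  # noise = 0, effect > 0: every planted-high signature score beats every low
  e0 <- gen_expression(n_cells = 80, n_genes = 20, noise = 0, seed = 1)
  s0 <- signature_score(normalize_expression(e0))
  hi <- attr(e0, "truth")$high_cells
  expect_gt(min(s0[hi]), max(s0[setdiff(names(s0), hi)]))
  # erm_anticorrelation = 0 effect: with factor 1 groups differ only by noise
  en <- gen_expression(n_cells = 2000, n_genes = 20, erm_anticorrelation = 1,
                       noise = 0.3, seed = 2)
  hi <- colnames(en) %in% attr(en, "truth")$high_cells
  d <- mean(en["EZR", hi]) - mean(en["EZR", !hi])
  expect_lt(abs(d) / mean(en["EZR", ]), 0.1)
})
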