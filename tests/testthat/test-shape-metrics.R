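# Shape descriptors and the deformability-cytometry gate.

test_that("roundness: circle, ellipse closed form, monotonicity", {
  expect_equal(roundness(contour(circle_poly(10, 2048))), 1, tolerance = 1e-4)
  expect_equal(roundness(contour(ellipse_poly(10, 5, 30, 2048))), 0.5,
               tolerance = 1e-4)
  # strictly decreasing in the axis ratio at fixed area
  ratios <- c(1, 1.5, 2, 3, 5)
  vals <- vapply(ratios, function(q) {
    b <- sqrt(100 / q)
    roundness(contour(ellipse_poly(q * b, b, 17, 1024)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # rasterized circle within 0.02
  sc <- gen_cell_scene(list(scene_object("disk", c(30, 30), radius_um = 10,
                                         intensity = c(g = 100))),
                       size_px = 128, pixel_size = 0.5, seed = 1)
  expect_equal(roundness(sc$truth$masks$cell), 1, tolerance = 0.02)
})

test_that("deformation: isoperimetric anchors and rigid invariance", {
  expect_lt(abs(deformation(contour(circle_poly(10, 4096)))), 1e-3)
  sq <- contour(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_equal(deformation(sq), 1 - sqrt(pi) / 2, tolerance = 1e-12)
  # 2:1 ellipse against the independent dense-polygon oracle
  v <- ellipse_poly(10, 5, 0, 8192)
  d_oracle <- 1 - 2 * sqrt(pi * oracle_area(v)) / oracle_perimeter(v)
  expect_equal(deformation(contour(ellipse_poly(10, 5, 40, 8192))), d_oracle,
               tolerance = 1e-6)
  # rigid motion + uniform scaling invariance on exact polygons
  set.seed(42)
  v <- star_poly(128)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  v2 <- sweep(3.2 * v %*% R, 2, c(11, -4), "+")
  expect_equal(deformation(contour(v2)), deformation(contour(v)),
               tolerance = 1e-9)
  expect_equal(roundness(contour(v2)), roundness(contour(v)),
               tolerance = 1e-6)
})

test_that("deformation is non-negative on random star-convex polygons", {
  set.seed(7)
  for (i in 1:200) {
    d <- deformation(contour(star_poly(128)))
    expect_gte(d, 0)
  }
})

test_that("porosity: convex unity, notched truth, rotation invariance", {
  expect_equal(porosity(contour(ellipse_poly(8, 5, 25, 1024))), 1,
               tolerance = 1e-3)
  notch <- gen_contours(6, "notched", seed = 3)
  impl <- vapply(notch$contours, porosity, numeric(1))
  expect_equal(impl, notch$truth$porosity, tolerance = 0.01)
  v <- notch$contours[[1]]$vertices
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(porosity(contour(v %*% R)), porosity(notch$contours[[1]]),
               tolerance = 1e-9)
})

test_that("rtdc_gate applies the porosity and area rules inclusively", {
  # circle of area 200 um^2 passes; area 100 fails on area
  c200 <- contour(circle_poly(sqrt(200 / pi), 512))
  c100 <- contour(circle_poly(sqrt(100 / pi), 512))
  g <- rtdc_gate(contour_set(list(c200, c100)))
  expect_equal(g$report$n_pass, 1L)
  expect_equal(g$report$table$reason, c("", "area"))
  # mixed synthetic set: counts match an independent brute-force filter
  set.seed(12)
  mixed <- contour_set(c(gen_contours(20, "circle", c(80, 450), seed = 1)$contours,
                         gen_contours(15, "ellipse", c(80, 450), seed = 2)$contours,
                         gen_contours(15, "notched", c(80, 450), seed = 3)$contours))
  g2 <- rtdc_gate(mixed)
  brute <- vapply(mixed$contours, function(ct) {
    v <- ct$vertices
    a <- oracle_area(v)
    p <- oracle_hull_area(v) / a
    p <= 1.05 && a >= 150 && a <= 350
  }, logical(1))
  expect_equal(g2$report$table$pass, brute)
  expect_equal(g2$report$n_pass + g2$report$n_fail_porosity +
                 g2$report$n_fail_area, g2$report$n_input)
  # idempotence
  g3 <- rtdc_gate(g2$passed)
  expect_equal(g3$report$n_pass, g3$report$n_input)
  # empty input
  g0 <- rtdc_gate(contour_set(list()))
  expect_equal(g0$report$n_input, 0L)
})
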