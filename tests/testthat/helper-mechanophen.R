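# Shared helpers. Geometry here is written independently of the package
# (plain shoelace / chull / closed forms) so it can serve as an oracle.

rel_rms <- function(a, b) {
  sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
}

# independent polygon area (shoelace) and perimeter
oracle_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
oracle_perimeter <- function(v) {
  vn <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  sum(sqrt(rowSums((vn - v)^2)))
}
oracle_hull_area <- function(v) {
  oracle_area(v[grDevices::chull(v[, 1], v[, 2]), , drop = FALSE])
}

circle_poly <- function(r = 10, n = 512, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_poly <- function(a, b, angle_deg = 0, n = 512) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- angle_deg * pi / 180
  x <- a * cos(th); y <- b * sin(th)
  cbind(x * cos(phi) - y * sin(phi), x * sin(phi) + y * cos(phi))
}

# random star-convex polygon with positive radius everywhere
star_poly <- function(n_vertices = 256, r0 = 10) {
  k <- 2:6
  amp <- runif(5, 0, 0.12)
  ph <- runif(5, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- r0 * (1 + colSums(amp * cos(outer(k, th) + ph)))
  stopifnot(all(r > 0))
  cbind(r * cos(th), r * sin(th))
}

# 90-degree counter-clockwise rotation of a square vector field
rot_field_90 <- function(field) {
  n <- nrow(field$vx)
  stopifnot(n == ncol(field$vx))
  rot <- function(m) {
    out <- matrix(0, n, n)
    for (i in seq_len(n)) out[i, ] <- m[, n + 1 - i]
    out
  }
  vector_field(-rot(field$vy), rot(field$vx), field$spacing,
               origin = field$origin, units = field$units)
}

# anisotropic contractile field T = -(x, y) * exp(-x^2/2sx2 - y^2/2sy2)
# on an n x n grid centered at zero: planted dipole eigenvalue ratio sx2/sy2
planted_dipole_field <- function(n = 128, h = 1, sx2 = 192, sy2 = 64,
                                 amp = 1) {
  x <- (seq_len(n) - 1 - (n - 1) / 2) * h
  X <- matrix(rep(x, each = n), n)
  Y <- matrix(rep(x, times = n), n)
  env <- exp(-0.5 * (X^2 / sx2 + Y^2 / sy2))
  vector_field(-amp * X * env, -amp * Y * env, h, units = "Pa")
}
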