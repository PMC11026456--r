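# Polygon primitives shared by shape metrics and the contour generators.

polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Contour area (shoelace formula)
#' @param ct a [contour()].
#' @return area in um^2.
#' @export
contour_area <- function(ct) abs(polygon_area_signed(ct$vertices))

#' Contour perimeter
#' @param ct a [contour()].
#' @return perimeter in um.
#' @export
contour_perimeter <- function(ct) {
  v <- ct$vertices
  vn <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  sum(sqrt(rowSums((vn - v)^2)))
}

#' Convex-hull area of a contour
#' @param ct a [contour()].
#' @return hull area in um^2.
#' @export
contour_hull_area <- function(ct) {
  v <- ct$vertices
  h <- grDevices::chull(v[, 1], v[, 2])
  abs(polygon_area_signed(v[h, , drop = FALSE]))
}

# Second central moments of the polygon interior (area moments, not vertex
# moments). Returns the 2x2 covariance matrix of the uniform distribution on
# the polygon: C = [[var_x, cov_xy], [cov_xy, var_y]].
polygon_covariance <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) stop("degenerate polygon")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # raw second moments about the origin
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central, normalized by area -> covariance of the uniform distribution
  vxx <- sxx / a - cx^2
  vyy <- syy / a - cy^2
  vxy <- sxy / a - cx * cy
  matrix(c(vxx, vxy, vxy, vyy), 2, 2)
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Dense polygon approximations of standard shapes (x, y in um).
polygon_circle <- function(center, radius, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

polygon_ellipse <- function(center, a, b, angle_deg = 0, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- angle_deg * pi / 180
  x0 <- a * cos(th); y0 <- b * sin(th)
  cbind(center[1] + x0 * cos(phi) - y0 * sin(phi),
        center[2] + x0 * sin(phi) + y0 * cos(phi))
}

# Star-shaped polygon from a radial profile r(theta); profile must be > 0.
polygon_star <- function(center, radius_fun, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- radius_fun(th)
  stopifnot(all(r > 0))
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Extract sub-pixel object contours from a label mask
#'
#' Traces the 0.5-level marching-squares isocontour of each labeled object,
#' giving sub-pixel polygon boundaries (pixel-edge counting overestimates
#' perimeters and would bias deformation upward).
#'
#' @param mask a [label_mask()].
#' @param labels which labels to trace (default all).
#' @return a [contour_set()] with one contour per label (the longest closed
#'   curve per object, in um).
#' @export
mask_contours <- function(mask, labels = NULL) {
  px <- attr(mask, "pixel_size")
  if (is.null(labels)) labels <- setdiff(sort(unique(as.integer(mask))), 0L)
  out <- vector("list", length(labels))
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with zeros so boundary objects still yield closed curves
  for (k in seq_along(labels)) {
    z <- matrix(0, nr + 2, nc + 2)
    z[2:(nr + 1), 2:(nc + 1)] <- (mask == labels[k]) * 1
    # contourLines treats z[x_index, y_index]: rows map to its x axis
    cl <- grDevices::contourLines(x = seq_len(nr + 2), y = seq_len(nc + 2),
                                  z = z, levels = 0.5)
    if (length(cl) == 0) stop("label ", labels[k], " produced no contour")
    len <- vapply(cl, function(cc) length(cc$x), numeric(1))
    cc <- cl[[which.max(len)]]
    # cc$x follows rows (y image axis), cc$y follows columns (x image axis);
    # subtract padding and convert 1-based pixel index to physical um
    vx <- (cc$y - 2) * px
    vy <- (cc$x - 2) * px
    out[[k]] <- contour(cbind(vx, vy), id = labels[k])
  }
  contour_set(out)
}
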