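# Active-wetting geometry: spherical-cap contact angles and cluster
# measurements from z-stacks.

#' Sphere radius of a spherical cap
#'
#' `R_sphere = (R^2 + H^2) / (2 H)` for a cap of contact radius `R` and
#' height `H`. As `H -> 0` at fixed `R` the sphere flattens
#' (`R_sphere -> Inf`).
#'
#' @param R contact radius in um (> 0).
#' @param H cap height in um (> 0).
#' @return sphere radius in um.
#' @export
sphere_radius <- function(R, H) {
  if (any(R <= 0) || any(H <= 0)) stop("R and H must be > 0")
  (R^2 + H^2) / (2 * H)
}

#' Contact angle of a cluster from spherical-cap geometry
#'
#' Wet clusters (`H <= R_sphere`) have `theta = asin(R / R_sphere)`; dewet
#' clusters (`H > R_sphere`) have `alpha = 180 - asin(R / R_sphere)`
#' (degrees). The two branches agree (90 deg) at the hemisphere `H = R`, so
#' the angle is continuous across the regime boundary. Cap geometry
#' guarantees `R <= R_sphere`, with equality exactly at the hemisphere.
#'
#' @param R contact radius in um.
#' @param H cluster height in um.
#' @return a `cluster_geometry` list: `R`, `H`, `sphere_radius`,
#'   `angle_deg` in (0, 180), `regime` (`"wet"` or `"dewet"`).
#' @export
contact_angle <- function(R, H) {
  rs <- sphere_radius(R, H)
  ratio <- R / rs
  if (ratio > 1 + 1e-9) stop("geometrically impossible cap: R > R_sphere")
  ratio <- min(ratio, 1)
  base <- asin(ratio) * 180 / pi
  wet <- H <= rs
  structure(list(R = R, H = H, sphere_radius = rs,
                 angle_deg = if (wet) base else 180 - base,
                 regime = if (wet) "wet" else "dewet"),
            class = "cluster_geometry")
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf("cluster_geometry: R %.4g um, H %.4g um, R_sphere %.4g um, %s, angle %.2f deg\n",
              x$R, x$H, x$sphere_radius, x$regime, x$angle_deg))
  invisible(x)
}

#' Measure contact radius and height of a cluster from a z-stack
#'
#' Thresholds the stack (Otsu on the full stack, or a supplied level),
#' takes the basal (substrate-plane) slice's largest connected object, and
#' reports its equivalent-circle radius `R = sqrt(A / pi)` together with the
#' height `H` from the topmost slice still containing the object. The
#' widest-plane radius is also reported: for dewet caps (angle > 90 deg) the
#' widest section lies above the substrate.
#'
#' @param stack an [image_stack()] with >= 3 slices.
#' @param substrate_plane index of the substrate slice (z = 0).
#' @param threshold `"otsu"` or a numeric intensity level.
#' @param min_pixels a slice counts as containing the object when at least
#'   this many pixels are above threshold.
#' @return list: `R_um`, `H_um`, `R_widest_um`, `geometry` (a
#'   [contact_angle()] result from the basal R and H).
#' @export
measure_cluster <- function(stack, substrate_plane = 1, threshold = "otsu",
                            min_pixels = 5) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  if (d[3] < 3) stop("stack needs >= 3 slices")
  px <- attr(stack, "pixel_size"); z_step <- attr(stack, "z_step")
  th <- if (identical(threshold, "otsu")) otsu_threshold(as.numeric(stack))
        else as.numeric(threshold)
  if (is.na(th)) stop("blank stack: cannot auto-threshold")
  basal <- stack[, , substrate_plane] > th
  if (sum(basal) < min_pixels) stop("object absent from basal slice")
  lab <- cc_label_cpp(basal, 8L)
  areas <- tabulate(lab[lab > 0], max(lab))
  biggest <- which.max(areas)
  a_basal <- areas[biggest] * px^2
  counts <- vapply(seq_len(d[3]), function(k) sum(stack[, , k] > th), numeric(1))
  above <- which(counts >= min_pixels)
  above <- above[above >= substrate_plane]
  top <- max(above)
  # the true apex lies between the last occupied slice and the next one;
  # the midpoint halves the worst-case quantization error
  H <- (top - substrate_plane + 0.5) * z_step
  a_widest <- max(counts[substrate_plane:top]) * px^2
  R <- sqrt(a_basal / pi)
  list(R_um = R, H_um = H, R_widest_um = sqrt(a_widest / pi),
       geometry = if (H > 0) contact_angle(R, H) else NULL)
}
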