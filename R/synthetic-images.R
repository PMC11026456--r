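# Synthetic microscopy: bead image pairs for TFM, multi-channel cell scenes,
# and spherical-cap cluster z-stacks, all with known ground truth.

# Render Gaussian spots (sub-resolution beads imaged through the PSF) onto a
# raster. Positions in um; sigma in px; analytic evaluation on a local patch.
render_spots <- function(n_row, n_col, pixel_size, positions_um, sigma_px,
                         amplitude, background) {
  img <- matrix(background, n_row, n_col)
  if (nrow(positions_um) == 0) return(img)
  half <- ceiling(4 * sigma_px)
  for (b in seq_len(nrow(positions_um))) {
    jc <- positions_um[b, 1] / pixel_size + 1  # x -> column (1-based, fractional)
    ic <- positions_um[b, 2] / pixel_size + 1
    j0 <- max(1L, floor(jc) - half); j1 <- min(n_col, floor(jc) + half + 1L)
    i0 <- max(1L, floor(ic) - half); i1 <- min(n_row, floor(ic) + half + 1L)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- exp(-0.5 * ((jj - jc) / sigma_px)^2)
    gy <- exp(-0.5 * ((ii - ic) / sigma_px)^2)
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gy, gx)
  }
  img
}

# Bilinear interpolation of a node-grid field at arbitrary (x, y) um points.
interp_bilinear <- function(values, spacing, origin, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  nr <- nrow(values); nc <- ncol(values)
  fj <- (x - origin[1]) / spacing + 1
  fi <- (y - origin[2]) / spacing + 1
  fj <- pmin(pmax(fj, 1), nc); fi <- pmin(pmax(fi, 1), nr)
  j0 <- pmin(floor(fj), nc - 1); i0 <- pmin(floor(fi), nr - 1)
  tj <- fj - j0; ti <- fi - i0
  v00 <- values[cbind(i0, j0)]; v01 <- values[cbind(i0, j0 + 1)]
  v10 <- values[cbind(i0 + 1, j0)]; v11 <- values[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - ti) * (1 - tj) + v01 * (1 - ti) * tj +
    v10 * ti * (1 - tj) + v11 * ti * tj
}

#' Synthetic bead image pair for traction force microscopy
#'
#' Generates a reference (relaxed gel) and deformed (gel under cell traction)
#' fluorescent-bead image with known ground truth. Beads are scattered
#' uniformly, rendered as isotropic Gaussian spots (0.2 um beads are below
#' the diffraction limit), and displaced by the forward elastic solution of
#' the supplied traction specification, interpolated at each bead position.
#'
#' @param truth a [traction_spec()], or `NULL` when `override_shift_um` is
#'   given.
#' @param substrate a [substrate_model()].
#' @param size_px image side length in pixels.
#' @param bead_density beads per um^2.
#' @param bead_sigma_px Gaussian spot s.d. in pixels.
#' @param bead_amplitude peak spot intensity above background.
#' @param background background intensity level.
#' @param noise_sd additive Gaussian read-noise s.d. (>= 0).
#' @param poisson_noise add Poisson shot noise before read noise.
#' @param seed integer seed; identical seeds give identical images.
#' @param field_stride compute the elastic field on a grid decimated by this
#'   factor (the displacement field is smooth; bead displacements are
#'   bilinearly interpolated).
#' @param method forward solver passed to [forward_displacement()].
#' @param override_shift_um optional `c(dx, dy)` um: apply this rigid shift to
#'   every bead instead of the elastic field (for PIV benchmarking).
#' @return list with `reference` and `deformed` ([raster_image()]),
#'   `truth` (bead positions before/after, the displacement field used, and
#'   the rendered traction field or shift).
#' @export
gen_bead_image_pair <- function(truth, substrate, size_px = 256,
                                bead_density = 0.03, bead_sigma_px = 1.5,
                                bead_amplitude = 150, background = 10,
                                noise_sd = 2, poisson_noise = FALSE,
                                seed = 1, field_stride = 2,
                                method = c("spectral", "direct_sum"),
                                override_shift_um = NULL) {
  method <- match.arg(method)
  if (bead_density <= 0) stop("bead_density must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  px <- substrate$pixel_size
  side_um <- size_px * px
  set.seed(seed)
  n_beads <- max(1L, round(bead_density * side_um^2))
  pos <- cbind(runif(n_beads, 0, side_um - px), runif(n_beads, 0, side_um - px))

  traction <- NULL; disp <- NULL
  if (!is.null(override_shift_um)) {
    u <- matrix(override_shift_um[1], n_beads, 1)
    shifted <- pos + cbind(rep(override_shift_um[1], n_beads),
                           rep(override_shift_um[2], n_beads))
  } else {
    stopifnot(inherits(truth, "traction_spec"))
    n_nodes <- max(2L, size_px %/% field_stride)
    spacing <- px * field_stride
    traction <- traction_field_from_spec(truth, n_nodes, spacing)
    disp <- forward_displacement(traction, substrate, method = method)
    ux <- interp_bilinear(disp$vx, spacing, disp$origin, pos[, 1], pos[, 2])
    uy <- interp_bilinear(disp$vy, spacing, disp$origin, pos[, 1], pos[, 2])
    shifted <- pos + cbind(ux, uy)
  }

  ref <- render_spots(size_px, size_px, px, pos, bead_sigma_px,
                      bead_amplitude, background)
  def <- render_spots(size_px, size_px, px, shifted, bead_sigma_px,
                      bead_amplitude, background)
  if (poisson_noise) {
    ref <- matrix(rpois(length(ref), pmax(ref, 0)), nrow(ref))
    def <- matrix(rpois(length(def), pmax(def, 0)), nrow(def))
  }
  if (noise_sd > 0) {
    ref <- ref + matrix(rnorm(length(ref), 0, noise_sd), nrow(ref))
    def <- def + matrix(rnorm(length(def), 0, noise_sd), nrow(def))
  }
  list(reference = raster_image(ref, px),
       deformed = raster_image(def, px),
       truth = list(bead_positions = pos, bead_positions_deformed = shifted,
                    traction = traction, displacement = disp,
                    override_shift_um = override_shift_um))
}

#' Scene object descriptor for [gen_cell_scene()]
#'
#' @param shape `"disk"` or `"ellipse"`.
#' @param center_um pair (x, y) in um.
#' @param radius_um disk radius in um (for `"disk"`).
#' @param semi_axes_um pair (a, b) semi-axes in um (for `"ellipse"`).
#' @param angle_deg ellipse orientation.
#' @param class object class: `"cell"`, `"nucleus"` or `"cluster"`.
#' @param intensity named numeric vector of per-channel intensities.
#' @param nucleus optional nested `scene_object` of class `"nucleus"` placed
#'   inside this object (shares its object id).
#' @return a `scene_object` descriptor.
#' @export
scene_object <- function(shape = c("disk", "ellipse"), center_um,
                         radius_um = NULL, semi_axes_um = NULL, angle_deg = 0,
                         class = c("cell", "nucleus", "cluster"),
                         intensity, nucleus = NULL) {
  shape <- match.arg(shape)
  class <- match.arg(class)
  if (shape == "disk" && is.null(radius_um)) stop("disk needs radius_um")
  if (shape == "ellipse" && is.null(semi_axes_um)) stop("ellipse needs semi_axes_um")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(shape = shape, center_um = center_um, radius_um = radius_um,
                 semi_axes_um = semi_axes_um, angle_deg = angle_deg,
                 class = class, intensity = intensity, nucleus = nucleus),
            class = "scene_object")
}

object_support <- function(obj, X, Y) {
  dx <- X - obj$center_um[1]; dy <- Y - obj$center_um[2]
  if (obj$shape == "disk") {
    dx^2 + dy^2 <= obj$radius_um^2
  } else {
    th <- obj$angle_deg * pi / 180
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    (xr / obj$semi_axes_um[1])^2 + (yr / obj$semi_axes_um[2])^2 <= 1
  }
}

#' Synthetic multi-channel cell/cluster scene with ground truth
#'
#' Renders objects (cells, nuclei, clusters) as flat-intensity shapes over a
#' uniform background, one raster per channel, and records exact ground-truth
#' masks and intensities before any noise is added. Objects of the same class
#' must not overlap.
#'
#' @param objects list of [scene_object()] descriptors.
#' @param size_px image side in pixels.
#' @param pixel_size um per pixel.
#' @param channels channel names; defaults to all channels named by any
#'   object intensity.
#' @param background background intensity (scalar or named per channel).
#' @param noise_sd additive Gaussian noise s.d.
#' @param seed integer seed.
#' @return list with `channels` (named list of [raster_image()]) and `truth`
#'   (per-class [label_mask()]s, an object table, and the background level).
#' @export
gen_cell_scene <- function(objects, size_px = 256, pixel_size = 0.5,
                           channels = NULL, background = 10, noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  if (is.null(channels)) {
    channels <- unique(unlist(lapply(objects, function(o) {
      c(names(o$intensity), if (!is.null(o$nucleus)) names(o$nucleus$intensity))
    })))
    if (length(channels) == 0) channels <- "gray"
  }
  bg <- if (length(background) == 1 && is.null(names(background)))
    stats::setNames(rep(background, length(channels)), channels)
  else stats::setNames(background[channels], channels)
  x <- (seq_len(size_px) - 1) * pixel_size
  X <- matrix(rep(x, each = size_px), size_px, size_px)
  Y <- matrix(rep(x, times = size_px), size_px, size_px)
  imgs <- lapply(bg, function(b) matrix(b, size_px, size_px))
  masks <- list(cell = matrix(0L, size_px, size_px),
                nucleus = matrix(0L, size_px, size_px),
                cluster = matrix(0L, size_px, size_px))
  rows <- list()
  next_id <- stats::setNames(c(0L, 0L, 0L), names(masks))
  paint <- function(obj, id) {
    sup <- object_support(obj, X, Y)
    if (any(masks[[obj$class]][sup] != 0L))
      stop("overlapping objects of class '", obj$class, "'")
    masks[[obj$class]][sup] <<- id
    for (ch in names(obj$intensity))
      if (ch %in% channels) imgs[[ch]][sup] <<- obj$intensity[[ch]]
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, class = obj$class, area_um2 = sum(sup) * pixel_size^2,
      area_px = sum(sup),
      t(vapply(channels, function(ch)
        if (ch %in% names(obj$intensity)) obj$intensity[[ch]] else NA_real_,
        numeric(1))))
  }
  for (obj in objects) {
    next_id[obj$class] <- next_id[obj$class] + 1L
    id <- next_id[[obj$class]]
    paint(obj, id)
    if (!is.null(obj$nucleus)) {
      nuc <- obj$nucleus
      nuc$class <- "nucleus"
      paint(nuc, id)
    }
  }
  if (noise_sd > 0)
    imgs <- lapply(imgs, function(m) m + matrix(rnorm(length(m), 0, noise_sd), nrow(m)))
  list(channels = lapply(imgs, raster_image, pixel_size = pixel_size),
       truth = list(
         masks = lapply(masks, label_mask, pixel_size = pixel_size),
         objects = if (length(rows)) do.call(rbind, rows) else
           data.frame(id = integer(0), class = character(0),
                      area_um2 = numeric(0), area_px = numeric(0)),
         background = bg))
}

#' Synthetic spherical-cap cluster z-stack
#'
#' Renders a cell cluster as a spherical cap of contact radius `R` and height
#' `H` sitting on the substrate plane (slice 1 at z = 0). The sphere radius
#' follows from the cap geometry, `R_sphere = (R^2 + H^2) / (2 H)`, and the
#' analytic contact angle is recorded as ground truth.
#'
#' @param contact_radius R, basal contact radius in um.
#' @param height H, cluster height in um.
#' @param z_step slice spacing in um.
#' @param pixel_size lateral pixel size in um.
#' @param size_px lateral image side in pixels (default fits the cap).
#' @param intensity,background object and background intensity levels.
#' @param noise_sd additive Gaussian noise s.d.
#' @param seed integer seed.
#' @return list with `stack` ([image_stack()]) and `truth` (R, H, R_sphere,
#'   angle in degrees, regime).
#' @export
gen_cluster_stack <- function(contact_radius, height, z_step = 0.5,
                              pixel_size = 0.5, size_px = NULL,
                              intensity = 100, background = 10,
                              noise_sd = 0, seed = 1) {
  R <- contact_radius; H <- height
  if (R <= 0 || H <= 0 || z_step <= 0) stop("R, H and z_step must be > 0")
  geom <- contact_angle(R, H)
  set.seed(seed)
  r_max <- max(R, if (geom$regime == "dewet") geom$sphere_radius else R)
  if (is.null(size_px)) size_px <- 2 * ceiling(r_max / pixel_size) + 21
  n_z <- floor(H / z_step) + 1L
  if (n_z < 3) stop("stack needs >= 3 slices; reduce z_step")
  cx <- (size_px - 1) / 2 * pixel_size
  x <- (seq_len(size_px) - 1) * pixel_size
  X <- matrix(rep(x, each = size_px), size_px, size_px)
  Y <- matrix(rep(x, times = size_px), size_px, size_px)
  r2 <- (X - cx)^2 + (Y - cx)^2
  zc <- H - geom$sphere_radius  # sphere center height (can be negative)
  arr <- array(background, c(size_px, size_px, n_z))
  for (k in seq_len(n_z)) {
    z <- (k - 1) * z_step
    rz2 <- geom$sphere_radius^2 - (z - zc)^2
    if (rz2 <= 0) next
    arr[, , k][r2 <= rz2] <- intensity
  }
  if (noise_sd > 0) arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim(arr))
  list(stack = image_stack(arr, pixel_size = pixel_size, z_step = z_step),
       truth = list(R = R, H = H, R_sphere = geom$sphere_radius,
                    angle_deg = geom$angle_deg, regime = geom$regime,
                    center_um = c(cx, cx)))
}
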