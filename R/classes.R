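#' mechanophen: mechanical phenotyping of cells and clusters from microscopy
#'
#' Traction force microscopy (PIV + Fourier-transform traction cytometry),
#' traction dipole anisotropy, shape and deformability metrics with
#' deformability-cytometry gating, active-wetting contact angles, intensity
#' quantification, centroid tracking, single-cell stemness-signature scoring,
#' and a synthetic-microscopy generator that produces every input with known
#' ground truth.
#'
#' @section Coordinate convention:
#' Rasters are R matrices indexed `[row, col]`; `x` runs along columns and
#' `y` along rows, the origin is the center of the top-left pixel, and
#' physical coordinates of pixel `(i, j)` are `x = (j - 1) * pixel_size`,
#' `y = (i - 1) * pixel_size` in micrometres.
#'
#' @useDynLib mechanophen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif rpois rnbinom rlnorm sd
#'   prcomp fft
#' @importFrom utils head read.csv write.csv
#' @keywords internal
"_PACKAGE"

#' Single-channel raster image
#'
#' A 2-D intensity raster with a physical pixel size.
#'
#' @param values numeric matrix of intensities (rows = y, cols = x).
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @return A `raster_image` object (matrix with `pixel_size` attribute).
#' @export
raster_image <- function(values, pixel_size = 1) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1, ncol(values) >= 1)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/pixel)")
  structure(values, pixel_size = pixel_size, class = c("raster_image", "matrix"))
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image: %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

#' Multi-slice image stack
#'
#' A z-stack of single-channel rasters with a physical pixel size and z-step.
#'
#' @param values 3-D numeric array `[row, col, slice]`.
#' @param pixel_size lateral pixel size in micrometres.
#' @param z_step axial slice spacing in micrometres.
#' @return An `image_stack` object.
#' @export
image_stack <- function(values, pixel_size = 1, z_step = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (pixel_size <= 0 || z_step <= 0) stop("pixel_size and z_step must be > 0")
  structure(values, pixel_size = pixel_size, z_step = z_step,
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("image_stack: %d x %d px, %d slices, %.4g um/px, z-step %.4g um\n",
              d[1], d[2], d[3], attr(x, "pixel_size"), attr(x, "z_step")))
  invisible(x)
}

#' Integer label mask
#'
#' Non-negative integer raster; 0 is background, positive labels are objects.
#'
#' @param labels integer matrix of labels.
#' @param pixel_size pixel size in micrometres.
#' @param border_labels optional integer vector of labels touching the border.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, pixel_size = 1, border_labels = integer(0)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  structure(labels, pixel_size = pixel_size, border_labels = border_labels,
            class = c("label_mask", "matrix"))
}

#' @export
print.label_mask <- function(x, ...) {
  n <- max(x)
  cat(sprintf("label_mask: %d x %d px, %d object(s), %.4g um/px\n",
              nrow(x), ncol(x), n, attr(x, "pixel_size")))
  invisible(x)
}

#' Number of labeled objects in a mask
#' @param mask a [label_mask()].
#' @return integer count of distinct positive labels.
#' @export
n_objects <- function(mask) {
  length(setdiff(unique(as.integer(mask)), 0L))
}

#' Regular-grid 2-D vector field
#'
#' Displacement (um) or traction (Pa) sampled on a regular rectangular grid.
#' Component matrices are indexed `[row, col]` with `x` along columns; node
#' physical coordinates are `origin + (index - 1) * spacing`.
#'
#' @param vx,vy numeric matrices: x- and y-components per node.
#' @param spacing grid spacing in micrometres.
#' @param origin length-2 numeric, physical (x, y) of node `[1, 1]` in um.
#' @param units `"um"` for displacement or `"Pa"` for traction.
#' @param valid optional logical matrix flagging trustworthy nodes.
#' @return A `vector_field` object (list).
#' @export
vector_field <- function(vx, vy, spacing, origin = c(0, 0), units = c("um", "Pa"),
                         valid = NULL) {
  vx <- as.matrix(vx); vy <- as.matrix(vy)
  units <- match.arg(units)
  if (!identical(dim(vx), dim(vy))) stop("vx and vy must have identical dimensions")
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(vx), ncol(vx))
  structure(list(vx = vx, vy = vy, spacing = spacing, origin = origin,
                 units = units, valid = valid),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$vx^2 + x$vy^2)
  cat(sprintf("vector_field [%s]: %d x %d nodes, spacing %.4g um, |v| mean %.4g max %.4g\n",
              x$units, nrow(x$vx), ncol(x$vx), x$spacing, mean(mag), max(mag)))
  invisible(x)
}

#' Node coordinates of a vector field
#' @param field a [vector_field()].
#' @return list with matrices `x` and `y` of node coordinates (um).
#' @export
field_coords <- function(field) {
  nr <- nrow(field$vx); nc <- ncol(field$vx)
  x <- matrix(rep(field$origin[1] + (seq_len(nc) - 1) * field$spacing, each = nr), nr, nc)
  y <- matrix(rep(field$origin[2] + (seq_len(nr) - 1) * field$spacing, times = nc), nr, nc)
  list(x = x, y = y)
}

#' Closed polygonal contour
#'
#' An ordered, closed polygon in micrometres with derived area, perimeter
#' and convex-hull area. Vertices are stored without repeating the first
#' point at the end.
#'
#' @param vertices two-column numeric matrix (x, y) in um, >= 3 rows.
#' @param id optional identifier.
#' @return A `contour` object.
#' @export
contour <- function(vertices, id = NA) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must be a two-column (x, y) matrix")
  # drop duplicated closing vertex if present
  n <- nrow(vertices)
  if (n >= 2 && all(abs(vertices[1, ] - vertices[n, ]) < 1e-12))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3) stop("a contour needs at least 3 distinct vertices")
  a <- polygon_area_signed(vertices)
  if (a < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  a <- abs(a)
  if (a <= 0) stop("degenerate contour: zero area")
  structure(list(vertices = vertices, id = id), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("contour%s: %d vertices, area %.4g um^2, perimeter %.4g um\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              nrow(x$vertices), contour_area(x), contour_perimeter(x)))
  invisible(x)
}

#' Set of contours with optional ground truth
#'
#' @param contours list of [contour()] objects.
#' @param truth optional data frame of per-contour ground truth.
#' @return A `contour_set` object.
#' @export
contour_set <- function(contours, truth = NULL) {
  stopifnot(is.list(contours), all(vapply(contours, inherits, TRUE, "contour")))
  structure(list(contours = contours, truth = truth), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d contour(s)%s\n", length(x$contours),
              if (is.null(x$truth)) "" else " with ground truth"))
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$contours)

#' Genes-by-cells expression matrix
#'
#' @param values non-negative numeric matrix, genes in rows, cells in columns.
#' @param state normalization state tag.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, state = c("raw", "normalized", "smoothed")) {
  values <- as.matrix(values)
  state <- match.arg(state)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene (row) and cell (column) identifiers are required")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and cell identifiers must be unique")
  structure(values, state = state, class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d cells\n",
              attr(x, "state"), nrow(x), ncol(x)))
  invisible(x)
}

#' Elastic substrate model
#'
#' Linear-elastic half-space description of a polyacrylamide gel substrate.
#' Young's moduli in the 0.5-30 kPa range are typical for these gels; the
#' incompressible limit (Poisson ratio 0.5) is the default convention.
#'
#' @param youngs_modulus Young's modulus E in Pa (> 0).
#' @param poisson_ratio Poisson ratio nu in `[0, 0.5]`.
#' @param pixel_size imaging pixel size in um/pixel.
#' @return A `substrate_model` object.
#' @export
substrate_model <- function(youngs_modulus, poisson_ratio = 0.5, pixel_size = 1) {
  if (youngs_modulus <= 0) stop("youngs_modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio > 0.5 + 1e-9)
    stop("poisson_ratio must lie in [0, 0.5]")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = min(poisson_ratio, 0.5),
                 pixel_size = pixel_size),
            class = "substrate_model")
}

#' @export
print.substrate_model <- function(x, ...) {
  cat(sprintf("substrate_model: E = %.4g Pa, nu = %.3g, %.4g um/px\n",
              x$youngs_modulus, x$poisson_ratio, x$pixel_size))
  invisible(x)
}
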