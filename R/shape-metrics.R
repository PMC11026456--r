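# Shape descriptors and deformability-cytometry gating.

region_moments <- function(region, label = NULL) {
  if (inherits(region, "contour")) {
    list(area = contour_area(region), cov = polygon_covariance(region$vertices))
  } else if (inherits(region, "label_mask")) {
    px <- attr(region, "pixel_size")
    if (is.null(label)) {
      labs <- setdiff(unique(as.integer(region)), 0L)
      if (length(labs) != 1) stop("mask holds ", length(labs),
                                  " objects; supply `label`")
      label <- labs
    }
    idx <- which(region == label, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("label ", label, " absent from mask")
    xy <- (idx[, c(2, 1)] - 1) * px
    # per-pixel uniform spread adds px^2/12 to each variance
    cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy) + diag(px^2 / 12, 2)
    list(area = nrow(idx) * px^2, cov = cv)
  } else stop("region must be a contour or a label_mask")
}

#' Roundness (best-fit-ellipse shape descriptor)
#'
#' `4 A / (pi * major_axis^2)` with the major axis taken from the ellipse
#' with the same second central moments as the region — the ImageJ/Fiji
#' "roundness" shape descriptor. 1 for a circle, `b/a` for an ellipse with
#' semi-axes `a >= b`.
#'
#' @param region a [contour()] or single-object [label_mask()].
#' @param label object label when `region` is a multi-object mask.
#' @return scalar in (0, 1].
#' @export
roundness <- function(region, label = NULL) {
  m <- region_moments(region, label)
  ev <- eigen(m$cov, symmetric = TRUE)$values
  major <- 4 * sqrt(max(ev))       # full major axis of the moment ellipse
  4 * m$area / (pi * major^2)
}

#' Deformation (one minus circularity)
#'
#' `1 - 2 sqrt(pi A) / P`, the deviation of the contour from a circle used in
#' real-time deformability cytometry; 0 for a circle by the isoperimetric
#' equality, positive for every other simple contour.
#'
#' @param ct a [contour()].
#' @return scalar in `[0, 1)`.
#' @export
deformation <- function(ct) {
  stopifnot(inherits(ct, "contour"))
  A <- contour_area(ct); P <- contour_perimeter(ct)
  if (A <= 0 || P <= 0) stop("degenerate contour")
  1 - 2 * sqrt(pi * A) / P
}

#' Porosity (convex-hull area over contour area)
#'
#' The deformability-cytometry contour-quality measure: 1 for convex
#' contours, > 1 when the contour has concavities (incomplete or noisy
#' contours).
#'
#' @param ct a [contour()].
#' @return scalar >= 1 (up to discretization).
#' @export
porosity <- function(ct) {
  stopifnot(inherits(ct, "contour"))
  A <- contour_area(ct)
  if (A <= 0) stop("degenerate contour")
  contour_hull_area(ct) / A
}

#' Deformability-cytometry quality gate
#'
#' A contour passes iff `porosity <= porosity_max` AND its area lies inside
#' `area_range` (bounds inclusive). Both conditions are evaluated for every
#' contour; the per-contour failure `reason` reports porosity first when both
#' fail.
#'
#' @param contours a [contour_set()].
#' @param porosity_max porosity cutoff (default 1.05).
#' @param area_range inclusive area gate in um^2 (default `c(150, 350)`).
#' @return list with `passed` (a [contour_set()]) and `report`
#'   (n_input/n_pass/n_fail_porosity/n_fail_area counts plus a per-contour
#'   table with pass flags and reasons).
#' @export
rtdc_gate <- function(contours, porosity_max = 1.05, area_range = c(150, 350)) {
  stopifnot(inherits(contours, "contour_set"))
  cts <- contours$contours
  n <- length(cts)
  if (n == 0) {
    rep0 <- list(n_input = 0L, n_pass = 0L, n_fail_porosity = 0L,
                 n_fail_area = 0L,
                 table = data.frame(id = integer(0), area_um2 = numeric(0),
                                    porosity = numeric(0), pass = logical(0),
                                    reason = character(0)))
    return(list(passed = contour_set(list()), report = rep0))
  }
  area <- vapply(cts, contour_area, numeric(1))
  poro <- vapply(cts, porosity, numeric(1))
  ok_p <- poro <= porosity_max
  ok_a <- area >= area_range[1] & area <= area_range[2]
  pass <- ok_p & ok_a
  reason <- ifelse(pass, "", ifelse(!ok_p, "porosity", "area"))
  ids <- vapply(cts, function(ct) if (is.na(ct$id)) NA_integer_ else as.integer(ct$id),
                integer(1))
  if (all(is.na(ids))) ids <- seq_len(n)
  tab <- data.frame(id = ids, area_um2 = area, porosity = poro,
                    pass = pass, reason = reason)
  list(passed = contour_set(cts[pass],
                            truth = if (!is.null(contours$truth))
                              contours$truth[pass, , drop = FALSE] else NULL),
       report = list(n_input = n, n_pass = sum(pass),
                     n_fail_porosity = sum(!ok_p),
                     n_fail_area = sum(ok_p & !ok_a),
                     table = tab))
}
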