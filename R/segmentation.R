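# Object segmentation and intensity quantification: thresholding,
# morphological clean-up, nuclear/cytoplasmic masks and background-subtracted
# mean intensities.

# Otsu's threshold on a 256-bin histogram.
otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), 256)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(w)
  m0 <- cumsum(w * mids)
  mt <- m0[256]
  between <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Local mean over a square block via an integral image (zero-padded edges
# renormalized by the true window size).
local_mean <- function(img, block) {
  b <- max(3L, as.integer(block)); if (b %% 2 == 0) b <- b + 1L
  r <- (b - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ii <- apply(cbind(0, rbind(0, img)), 2, cumsum)
  ii <- t(apply(ii, 1, cumsum))
  idx <- function(v, n) pmin(pmax(v, 0L), n)
  i1 <- idx(seq_len(nr) + r, nr); i0 <- idx(seq_len(nr) - r - 1L, nr)
  j1 <- idx(seq_len(nc) + r, nc); j0 <- idx(seq_len(nc) - r - 1L, nc)
  S <- ii[i1 + 1L, j1 + 1L] - ii[i0 + 1L, j1 + 1L] -
       ii[i1 + 1L, j0 + 1L] + ii[i0 + 1L, j0 + 1L]
  cnt <- outer(i1 - i0, j1 - j0)
  S / cnt
}

# Background components not reaching the image border are holes.
fill_holes <- function(binary) {
  bg <- cc_label_cpp(!binary, 4L)
  border <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])), 0L)
  holes <- bg != 0L & !matrix(bg %in% border, nrow(bg), ncol(bg))
  binary | holes
}

#' Segment objects in a single-channel image
#'
#' Threshold (global Otsu, a fixed level, or locally adaptive mean), then
#' morphological closing, hole filling, small-object removal and
#' connected-component labeling. Objects touching the image border are
#' flagged (`attr(, "border_labels")`) rather than silently dropped, along
#' with area outliers beyond 3 MAD (`attr(, "area_outlier_labels")`).
#'
#' @param image a [raster_image()] (single channel).
#' @param method `"otsu"`, `"adaptive"`, or a numeric global threshold level.
#' @param adaptive_block block size in px for the adaptive local mean.
#' @param adaptive_offset subtracted from the local mean before comparison.
#' @param min_area minimum object area in um^2.
#' @param closing_radius disk radius (px) of the morphological closing.
#' @param connectivity 4 or 8 (default 8).
#' @return a [label_mask()]; a blank image yields an empty mask with a
#'   warning.
#' @export
segment_objects <- function(image, method = "otsu", adaptive_block = 51,
                            adaptive_offset = 0, min_area = 20,
                            closing_radius = 2, connectivity = 8) {
  stopifnot(inherits(image, "raster_image"))
  px <- attr(image, "pixel_size")
  vals <- unclass(image); attributes(vals) <- list(dim = dim(image))
  if (is.numeric(method)) {
    binary <- vals > method
  } else if (method == "otsu") {
    th <- otsu_threshold(vals)
    if (is.na(th)) {
      warning("blank image: all intensities equal; returning empty mask")
      return(label_mask(matrix(0L, nrow(vals), ncol(vals)), px))
    }
    binary <- vals > th
  } else if (method == "adaptive") {
    binary <- vals > (local_mean(vals, adaptive_block) - adaptive_offset)
  } else stop("unknown threshold method: ", method)
  if (closing_radius > 0) {
    binary <- morph_disk_cpp(binary, closing_radius, TRUE)
    binary <- morph_disk_cpp(binary, closing_radius, FALSE)
  }
  binary <- fill_holes(binary)
  lab <- cc_label_cpp(binary, as.integer(connectivity))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab)) * px^2
    keep <- which(areas >= min_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  border <- sort(setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                  lab[, 1], lab[, ncol(lab)])), 0L))
  out <- label_mask(lab, px, border_labels = border)
  n <- max(lab)
  if (n >= 3) {
    areas <- tabulate(lab[lab > 0], n)
    dev <- abs(areas - median(areas))
    madv <- median(dev)
    attr(out, "area_outlier_labels") <-
      if (madv > 0) which(dev > 3 * 1.4826 * madv) else integer(0)
  } else attr(out, "area_outlier_labels") <- integer(0)
  out
}

#' Cytoplasmic mask: cell support minus nucleus support
#'
#' Multiplies the cell mask by the inverted nucleus mask; cytoplasm pixels
#' inherit the cell label. Cells whose cytoplasm comes out empty are flagged
#' in `attr(, "empty_labels")`.
#'
#' @param cell,nucleus aligned [label_mask()]s of the same shape.
#' @return a [label_mask()] of the cytoplasm.
#' @export
cytoplasm_mask <- function(cell, nucleus) {
  if (!identical(dim(cell), dim(nucleus))) stop("mask shapes differ")
  cyto <- unclass(cell); attributes(cyto) <- list(dim = dim(cell))
  cyto[nucleus != 0L] <- 0L
  labs <- setdiff(unique(as.integer(cell)), 0L)
  empty <- sort(labs[!(labs %in% cyto)])
  out <- label_mask(cyto, attr(cell, "pixel_size"))
  attr(out, "empty_labels") <- empty
  out
}

#' Background-subtracted mean intensities per labeled object
#'
#' Background is either a supplied scalar or estimated automatically as the
#' median intensity of the complement of the (2 px dilated) mask. Negative
#' background-subtracted means are clamped to zero with a warning unless
#' `allow_negative = TRUE`.
#'
#' @param image a [raster_image()].
#' @param mask a [label_mask()] aligned to `image`.
#' @param background `"auto"` or a numeric level.
#' @param labels labels to measure (default all); a requested label absent
#'   from the mask is an error.
#' @param allow_negative keep negative subtracted means.
#' @return data frame: object_id, mean_intensity, background,
#'   background_subtracted_mean.
#' @export
mean_intensity <- function(image, mask, background = "auto", labels = NULL,
                           allow_negative = FALSE) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  present <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (is.null(labels)) labels <- present
  missing <- setdiff(labels, present)
  if (length(missing)) stop("label(s) absent from mask: ", paste(missing, collapse = ", "))
  if (length(labels) == 0) stop("mask is empty")
  bg <- if (identical(background, "auto")) {
    comp <- !morph_disk_cpp(mask != 0L, 2, TRUE)
    if (!any(comp)) stop("mask covers the whole image; supply a background level")
    median(image[comp])
  } else as.numeric(background)
  mu <- vapply(labels, function(l) mean(image[mask == l]), numeric(1))
  sub <- mu - bg
  if (!allow_negative && any(sub < 0)) {
    warning("negative background-subtracted mean(s) clamped to 0")
    sub <- pmax(sub, 0)
  }
  data.frame(object_id = labels, mean_intensity = mu, background = bg,
             background_subtracted_mean = sub)
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Ratio of the mean intensity over the nuclear mask to the mean over the
#' cytoplasmic mask, per object id shared by the two masks. A zero
#' cytoplasmic mean yields `NA` with a warning.
#'
#' @param image a [raster_image()] (e.g. the YAP channel).
#' @param nucleus,cytoplasm aligned [label_mask()]s.
#' @return data frame: object_id, nuclear_mean, cytoplasmic_mean, ratio.
#' @export
yap_ratio <- function(image, nucleus, cytoplasm) {
  if (!identical(dim(nucleus), dim(cytoplasm))) stop("mask shapes differ")
  labs <- intersect(setdiff(unique(as.integer(nucleus)), 0L),
                    setdiff(unique(as.integer(cytoplasm)), 0L))
  if (length(labs) == 0) stop("no object id present in both masks")
  labs <- sort(labs)
  nm <- vapply(labs, function(l) mean(image[nucleus == l]), numeric(1))
  cm <- vapply(labs, function(l) mean(image[cytoplasm == l]), numeric(1))
  ratio <- nm / cm
  if (any(cm == 0)) {
    warning("zero cytoplasmic mean: ratio undefined for some object(s)")
    ratio[cm == 0] <- NA_real_
  }
  data.frame(object_id = labs, nuclear_mean = nm, cytoplasmic_mean = cm,
             ratio = ratio)
}

#' Mean masked intensity across selected z planes
#'
#' Resolves each requested plane offset (um above the reference slice) to the
#' nearest stack slice, computes the masked mean per plane, and averages the
#' per-plane means.
#'
#' @param stack an [image_stack()].
#' @param mask a logical matrix or [label_mask()] (nonzero = measured).
#' @param plane_offsets offsets in um above the reference slice.
#' @param reference_slice index of the z = 0 slice.
#' @return scalar mean intensity.
#' @export
plane_intensity_profile <- function(stack, mask, plane_offsets,
                                    reference_slice = 1) {
  z_step <- attr(stack, "z_step")
  n_z <- dim(stack)[3]
  idx <- reference_slice + round(plane_offsets / z_step)
  if (any(idx < 1 | idx > n_z))
    stop("plane offset beyond stack range (", n_z, " slices, z-step ", z_step, " um)")
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  mean(vapply(idx, function(k) mean(stack[, , k][m]), numeric(1)))
}
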