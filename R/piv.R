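# Particle image velocimetry: window-wise zero-mean cross-correlation with
# sub-pixel peak refinement, spurious-vector validation, and iterative
# image-deformation passes for spatially varying fields.

#' PIV parameters
#'
#' @param window square interrogation-window side in px (>= 8; default 32,
#'   the standard bead-image setting).
#' @param overlap window overlap fraction in `[0, 1)` (default 0.5).
#' @param max_displacement largest admissible displacement in px (default
#'   `window / 4`).
#' @param subpixel `"gaussian"` (three-point log fit) or `"parabolic"`.
#' @param peak_ratio_min minimum first-to-second correlation peak ratio; a
#'   lower ratio flags the vector as spurious.
#' @param median_limit_px residual against the local median (px) above which
#'   a vector is flagged and replaced.
#' @param passes number of image-deformation passes (>= 1). Passes beyond
#'   the first warp the deformed image by the current displacement estimate
#'   and correlate the residual, which removes the window-averaging bias a
#'   single pass suffers on spatially varying fields.
#' @return a `piv_params` object.
#' @export
piv_params <- function(window = 32L, overlap = 0.5, max_displacement = NULL,
                       subpixel = c("gaussian", "parabolic"),
                       peak_ratio_min = 1.05, median_limit_px = 2,
                       passes = 3L) {
  window <- as.integer(window)
  if (window < 8L) stop("window must be >= 8 px")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (is.null(max_displacement)) max_displacement <- window / 4
  if (passes < 1) stop("passes must be >= 1")
  structure(list(window = window, overlap = overlap,
                 max_displacement = max_displacement,
                 subpixel = match.arg(subpixel),
                 peak_ratio_min = peak_ratio_min,
                 median_limit_px = median_limit_px,
                 passes = as.integer(passes)),
            class = "piv_params")
}

# Three-point sub-pixel offset around an interior peak.
subpixel_offset <- function(cl, cc, cr, method) {
  if (method == "gaussian" && cl > 0 && cc > 0 && cr > 0) {
    d <- log(cl) + log(cr) - 2 * log(cc)
    if (d < 0) return(0.5 * (log(cl) - log(cr)) / d)
  }
  d <- cl + cr - 2 * cc
  if (d < 0) 0.5 * (cl - cr) / d else 0
}

# Catmull-Rom bicubic sampling of a matrix at fractional (row, col) indices;
# clamped at the borders. Used to warp bead images without the blur and
# centroid bias of bilinear resampling.
interp_bicubic <- function(values, fi, fj) {
  nr <- nrow(values); nc <- ncol(values)
  fi <- pmin(pmax(as.numeric(fi), 1), nr)
  fj <- pmin(pmax(as.numeric(fj), 1), nc)
  i0 <- pmin(pmax(floor(fi), 1L), nr)
  j0 <- pmin(pmax(floor(fj), 1L), nc)
  ti <- fi - i0; tj <- fj - j0
  wcub <- function(t) {
    # Catmull-Rom weights for offsets -1, 0, 1, 2
    t2 <- t * t; t3 <- t2 * t
    cbind(-0.5 * t3 + t2 - 0.5 * t,
          1.5 * t3 - 2.5 * t2 + 1,
          -1.5 * t3 + 2 * t2 + 0.5 * t,
          0.5 * t3 - 0.5 * t2)
  }
  wi <- wcub(ti); wj <- wcub(tj)
  clampi <- function(v) pmin(pmax(v, 1L), nr)
  clampj <- function(v) pmin(pmax(v, 1L), nc)
  out <- numeric(length(fi))
  for (a in 1:4) {
    row_a <- clampi(i0 + (a - 2L))
    acc <- numeric(length(fi))
    for (b in 1:4) {
      col_b <- clampj(j0 + (b - 2L))
      acc <- acc + wj[, b] * values[cbind(row_a, col_b)]
    }
    out <- out + wi[, a] * acc
  }
  out
}

# One correlation pass between two plain matrices on the window grid
# defined by top-left indices i0s/j0s. Returns px displacements + validity.
piv_single_pass <- function(ref, def, params, i0s, j0s, mrange) {
  w <- params$window
  s <- 2L * w
  lags <- seq(-floor(mrange), floor(mrange))
  lag_idx <- function(d) ((d %% s) + 1L)
  ovl <- outer(w - abs(lags), w - abs(lags))
  dx <- matrix(0, length(i0s), length(j0s))
  dy <- matrix(0, length(i0s), length(j0s))
  valid <- matrix(TRUE, length(i0s), length(j0s))
  for (a in seq_along(i0s)) {
    for (b in seq_along(j0s)) {
      ri <- i0s[a]:(i0s[a] + w - 1L); rj <- j0s[b]:(j0s[b] + w - 1L)
      A <- ref[ri, rj]; B <- def[ri, rj]
      A <- A - mean(A); B <- B - mean(B)
      if (sd(A) == 0 || sd(B) == 0) { valid[a, b] <- FALSE; next }
      PA <- matrix(0, s, s); PB <- matrix(0, s, s)
      PA[1:w, 1:w] <- A; PB[1:w, 1:w] <- B
      corr <- Re(fft(Conj(fft(PA)) * fft(PB), inverse = TRUE)) / (s * s)
      # corr at circular index (dy, dx) = sum A[i,j] B[i+dy, j+dx];
      # normalize by the overlap count so larger lags are not biased low
      sub <- corr[lag_idx(lags), lag_idx(lags)] / ovl
      pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      pi_ <- pk[1]; pj_ <- pk[2]
      # peak-ratio validation: second peak outside a 3x3 neighborhood
      masked <- sub
      masked[max(1, pi_ - 1):min(nrow(sub), pi_ + 1),
             max(1, pj_ - 1):min(ncol(sub), pj_ + 1)] <- -Inf
      p2 <- max(masked)
      if (is.finite(p2) && p2 > 0 && sub[pi_, pj_] / p2 < params$peak_ratio_min)
        valid[a, b] <- FALSE
      off_y <- if (pi_ > 1 && pi_ < nrow(sub))
        subpixel_offset(sub[pi_ - 1, pj_], sub[pi_, pj_], sub[pi_ + 1, pj_],
                        params$subpixel) else 0
      off_x <- if (pj_ > 1 && pj_ < ncol(sub))
        subpixel_offset(sub[pi_, pj_ - 1], sub[pi_, pj_], sub[pi_, pj_ + 1],
                        params$subpixel) else 0
      dy[a, b] <- lags[pi_] + off_y
      dx[a, b] <- lags[pj_] + off_x
    }
  }
  list(dx = dx, dy = dy, valid = valid)
}

# Local-median validation and replacement; returns updated fields + flags.
piv_validate <- function(dx, dy, valid, params) {
  med_nb <- function(m, a, b, ok) {
    ia <- max(1, a - 1):min(nrow(m), a + 1)
    jb <- max(1, b - 1):min(ncol(m), b + 1)
    median(m[ia, jb][ok[ia, jb]], na.rm = TRUE)
  }
  for (a in seq_len(nrow(dx))) for (b in seq_len(ncol(dx))) {
    if (!valid[a, b]) next
    mx <- med_nb(dx, a, b, valid); my <- med_nb(dy, a, b, valid)
    if (is.finite(mx) && is.finite(my) &&
        (abs(dx[a, b] - mx) > params$median_limit_px ||
         abs(dy[a, b] - my) > params$median_limit_px))
      valid[a, b] <- FALSE
  }
  if (any(!valid) && any(valid)) {
    for (a in seq_len(nrow(dx))) for (b in seq_len(ncol(dx))) {
      if (valid[a, b]) next
      mx <- med_nb(dx, a, b, valid); my <- med_nb(dy, a, b, valid)
      dx[a, b] <- if (is.finite(mx)) mx else median(dx[valid])
      dy[a, b] <- if (is.finite(my)) my else median(dy[valid])
    }
  }
  list(dx = dx, dy = dy, valid = valid)
}

#' Displacement field between two bead images by PIV
#'
#' Splits both images into square interrogation windows, cross-correlates
#' each reference/deformed window pair (zero-mean, FFT-based, zero-padded so
#' the correlation is non-circular and overlap-normalized so it is
#' unbiased), locates the peak within the admissible range, and refines it
#' to sub-pixel precision. Vectors with a low first-to-second peak ratio or
#' deviating from the local median beyond `median_limit_px` are flagged
#' invalid and replaced by the local median. When `params$passes > 1`, the
#' deformed image is warped by the current displacement estimate and the
#' residual re-correlated (iterative image deformation), which removes the
#' window-averaging bias on smoothly varying fields.
#'
#' @param reference,deformed [raster_image()]s of identical shape.
#' @param params a [piv_params()].
#' @return a [vector_field()] of displacements in um on the window-center
#'   grid (spacing `window * (1 - overlap)` px); `$valid` flags vectors that
#'   were measured rather than replaced.
#' @export
piv_displacement <- function(reference, deformed, params = piv_params()) {
  stopifnot(inherits(reference, "raster_image"), inherits(deformed, "raster_image"))
  if (!identical(dim(reference), dim(deformed))) stop("image shapes differ")
  px <- attr(reference, "pixel_size")
  w <- params$window
  nr <- nrow(reference); nc <- ncol(reference)
  if (nr < w || nc < w) stop("image smaller than one interrogation window")
  if (sd(reference) == 0 || sd(deformed) == 0) stop("blank image")
  step <- max(1L, as.integer(round(w * (1 - params$overlap))))
  i0s <- seq(1L, nr - w + 1L, by = step)
  j0s <- seq(1L, nc - w + 1L, by = step)
  centers_i <- i0s + (w - 1) / 2
  centers_j <- j0s + (w - 1) / 2
  mrange <- min(params$max_displacement, w - 1)
  ref <- unclass(reference); attributes(ref) <- list(dim = dim(reference))
  def <- unclass(deformed); attributes(def) <- list(dim = dim(deformed))
  ux <- matrix(0, length(i0s), length(j0s))  # accumulated, px
  uy <- matrix(0, length(i0s), length(j0s))
  valid <- matrix(TRUE, length(i0s), length(j0s))
  II <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  JJ <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (pass in seq_len(params$passes)) {
    frozen <- matrix(FALSE, length(i0s), length(j0s))
    if (pass == 1) {
      def_w <- def
    } else {
      # warp deformed image by the current estimate: sample def at x + u(x);
      # bicubic field interpolation captures curvature between nodes
      fi <- (II - centers_i[1]) / step + 1
      fj <- (JJ - centers_j[1]) / step + 1
      ux_px <- matrix(interp_bicubic(ux, fi, fj), nr, nc)
      uy_px <- matrix(interp_bicubic(uy, fi, fj), nr, nc)
      def_w <- matrix(interp_bicubic(def, II + uy_px, JJ + ux_px), nr, nc)
      # windows whose warp sampled outside the image (clamped values) keep
      # their current estimate instead of a corrupted residual
      oob <- (II + uy_px) < 1 | (II + uy_px) > nr |
             (JJ + ux_px) < 1 | (JJ + ux_px) > nc
      for (a in seq_along(i0s)) for (b in seq_along(j0s))
        frozen[a, b] <- any(oob[i0s[a]:(i0s[a] + w - 1L),
                                j0s[b]:(j0s[b] + w - 1L)])
    }
    res <- piv_single_pass(ref, def_w, params, i0s, j0s,
                           if (pass == 1) mrange else max(2, mrange / 4))
    res <- piv_validate(res$dx, res$dy, res$valid, params)
    ux <- ux + ifelse(frozen, 0, res$dx)
    uy <- uy + ifelse(frozen, 0, res$dy)
    valid <- valid & (res$valid | frozen)
  }
  vector_field(ux * px, uy * px, spacing = step * px,
               origin = c((centers_j[1] - 1) * px, (centers_i[1] - 1) * px),
               units = "um", valid = valid)
}
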