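# Fourier-transform traction cytometry: regularized inversion of the
# Boussinesq operator, plus traction summaries.

# Fill invalid nodes by iterative neighborhood averaging (handles interior
# gaps and, degenerately, whole-row gaps).
fill_gaps <- function(vx, vy, valid) {
  if (all(valid)) return(list(vx = vx, vy = vy))
  for (iter in 1:1000) {
    todo <- which(!valid, arr.ind = TRUE)
    if (nrow(todo) == 0) break
    progressed <- FALSE
    for (r in seq_len(nrow(todo))) {
      a <- todo[r, 1]; b <- todo[r, 2]
      ia <- max(1, a - 1):min(nrow(vx), a + 1)
      jb <- max(1, b - 1):min(ncol(vx), b + 1)
      nb <- valid[ia, jb]
      if (any(nb)) {
        vx[a, b] <- mean(vx[ia, jb][nb])
        vy[a, b] <- mean(vy[ia, jb][nb])
        valid[a, b] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("no valid nodes to fill gaps from")
  }
  list(vx = vx, vy = vy)
}

reflect_pad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(p, nr - 1)) + 1), seq_len(nr),
          nr - seq_len(min(p, nr - 1)))
  ci <- c(rev(seq_len(min(p, nc - 1)) + 1), seq_len(nc),
          nc - seq_len(min(p, nc - 1)))
  m[ri, ci]
}

#' Traction field from a displacement field (regularized FTTC)
#'
#' Inverts the Boussinesq half-space operator in the Fourier domain with
#' zeroth-order Tikhonov regularization: per wavevector,
#' `t_hat = (G^T G + lambda^2 I)^-1 G^T u_hat`. The zero-frequency traction
#' is set to zero (a rigid substrate translation is unobservable, so the
#' net-force-free convention is adopted). Invalid displacement nodes are
#' filled by neighborhood interpolation first. The recovered traction is the
#' stress exerted by the cell on the gel.
#'
#' @param displacement a [vector_field()] in um on a regular grid.
#' @param substrate a [substrate_model()].
#' @param lambda Tikhonov parameter (units of G, um/Pa); default
#'   `1e-9 * E`. Must be >= 0.
#' @param pad reflect-pad by half the field per side before the FFT to
#'   reduce periodicity artifacts (default `TRUE`; disable for exactness
#'   tests).
#' @param reg_order 0 (default) penalizes traction amplitude uniformly in k;
#'   1 penalizes the traction gradient (`lambda^2 k^2`), which preserves the
#'   low-frequency amplitude better on noisy displacement data (for order 1,
#'   `lambda` has units of um * G).
#' @return a [vector_field()] with units `"Pa"` on the displacement grid.
#' @export
fttc_tractions <- function(displacement, substrate, lambda = NULL, pad = TRUE,
                           reg_order = 0) {
  stopifnot(inherits(displacement, "vector_field"),
            inherits(substrate, "substrate_model"))
  if (displacement$units != "um") stop("displacement field must have units 'um'")
  E <- substrate$youngs_modulus; nu <- substrate$poisson_ratio
  if (is.null(lambda)) lambda <- 1e-9 * E
  if (lambda < 0) stop("lambda must be >= 0")
  if (any(!is.finite(displacement$vx[displacement$valid])) ||
      any(!is.finite(displacement$vy[displacement$valid])))
    stop("non-finite displacement values")
  filled <- fill_gaps(displacement$vx, displacement$vy, displacement$valid)
  ux <- filled$vx; uy <- filled$vy
  ny <- nrow(ux); nx <- ncol(ux)
  p <- if (pad) floor(min(ny, nx) / 2) else 0L
  if (p > 0) { ux <- reflect_pad(ux, p); uy <- reflect_pad(uy, p) }
  G <- boussinesq_greens_ft(ncol(ux), nrow(ux), displacement$spacing, E, nu)
  uxh <- fft2(ux); uyh <- fft2(uy)
  # w = G^T u_hat (G symmetric)
  wx <- G$gxx * uxh + G$gxy * uyh
  wy <- G$gxy * uxh + G$gyy * uyh
  kx <- 2 * pi * fft_freq(ncol(ux), displacement$spacing)
  ky <- 2 * pi * fft_freq(nrow(ux), displacement$spacing)
  K2 <- outer(ky^2, kx^2, "+")
  pen <- if (reg_order == 0) lambda^2 else lambda^2 * K2
  m11 <- G$gxx^2 + G$gxy^2 + pen
  m12 <- G$gxy * (G$gxx + G$gyy)
  m22 <- G$gyy^2 + G$gxy^2 + pen
  det <- m11 * m22 - m12^2
  det[det == 0] <- Inf
  txh <- (m22 * wx - m12 * wy) / det
  tyh <- (m11 * wy - m12 * wx) / det
  txh[1, 1] <- 0; tyh[1, 1] <- 0
  tx <- Re(ifft2(txh)); ty <- Re(ifft2(tyh))
  if (p > 0) {
    rows <- p + seq_len(ny); cols <- p + seq_len(nx)
    tx <- tx[rows, cols]; ty <- ty[rows, cols]
  }
  vector_field(tx, ty, spacing = displacement$spacing,
               origin = displacement$origin, units = "Pa")
}

#' Automatic regularization choice for FTTC by the L-curve corner
#'
#' Sweeps a logarithmic grid of regularization parameters, traces the
#' L-curve (log residual norm versus log solution seminorm, both computed
#' per Fourier mode), discards the flat low-lambda plateau where
#' regularization is inactive (residual within 10 percent of its minimum),
#' and returns the lambda of maximum curvature on the ascending branch.
#'
#' @param displacement a [vector_field()] in um.
#' @param substrate a [substrate_model()].
#' @param reg_order 0 or 1, as in [fttc_tractions()].
#' @param lambdas optional vector of candidate lambdas (default: 120 points
#'   spanning 1e-5 to 10 times the scale `1/(E k_nyq)`-based heuristic).
#' @return the selected lambda (scalar).
#' @export
fttc_select_lambda <- function(displacement, substrate, reg_order = 1,
                               lambdas = NULL) {
  E <- substrate$youngs_modulus; nu <- substrate$poisson_ratio
  filled <- fill_gaps(displacement$vx, displacement$vy, displacement$valid)
  ux <- filled$vx; uy <- filled$vy
  ny <- nrow(ux); nx <- ncol(ux)
  h <- displacement$spacing
  G <- boussinesq_greens_ft(nx, ny, h, E, nu)
  K2 <- outer((2 * pi * fft_freq(ny, h))^2, (2 * pi * fft_freq(nx, h))^2, "+")
  uxh <- fft2(ux); uyh <- fft2(uy)
  # eigen-decomposition of the symmetric 2x2 G per mode
  trm <- (G$gxx + G$gyy) / 2; dif <- (G$gxx - G$gyy) / 2
  disc <- sqrt(dif^2 + G$gxy^2)
  g1 <- trm + disc; g2 <- trm - disc
  v1x <- ifelse(abs(G$gxy) > 1e-300, G$gxy, 1)
  v1y <- ifelse(abs(G$gxy) > 1e-300, g1 - G$gxx, 0)
  nrm <- sqrt(v1x^2 + v1y^2)
  v1x <- v1x / nrm; v1y <- v1y / nrm
  c1 <- v1x * uxh + v1y * uyh
  c2 <- -v1y * uxh + v1x * uyh
  if (is.null(lambdas)) {
    k_nyq <- pi / h
    scale <- if (reg_order == 0) 3 / (E * k_nyq) else 3 / (E * k_nyq^2)
    lambdas <- scale * 10^seq(-2.5, 2.5, length.out = 120)
  }
  rho <- eta <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    pen <- if (reg_order == 0) lambdas[i]^2 else lambdas[i]^2 * K2
    f1 <- g1^2 / (g1^2 + pen); f2 <- g2^2 / (g2^2 + pen)
    f1[1, 1] <- 0; f2[1, 1] <- 0
    t1 <- ifelse(g1 != 0, f1 / g1, 0) * c1
    t2 <- ifelse(g2 != 0, f2 / g2, 0) * c2
    rho[i] <- sqrt(sum(Mod((1 - f1) * c1)^2 + Mod((1 - f2) * c2)^2))
    sem <- if (reg_order == 0) (Mod(t1)^2 + Mod(t2)^2)
           else K2 * (Mod(t1)^2 + Mod(t2)^2)
    eta[i] <- sqrt(sum(sem))
  }
  keep <- rho > 1.1 * min(rho[rho > 0]) & eta > 0
  lr <- log(rho); le <- log(eta)
  curv <- rep(NA_real_, length(lambdas))
  for (i in 2:(length(lambdas) - 1)) {
    d1r <- (lr[i + 1] - lr[i - 1]) / 2; d1e <- (le[i + 1] - le[i - 1]) / 2
    d2r <- lr[i + 1] - 2 * lr[i] + lr[i - 1]
    d2e <- le[i + 1] - 2 * le[i] + le[i - 1]
    curv[i] <- (d1r * d2e - d1e * d2r) / (d1r^2 + d1e^2)^1.5
  }
  # the curve typically shows two knees: a small one where regularization
  # starts absorbing noise and the macroscopic corner where it starts
  # removing signal; take the positive-curvature local maximum with the
  # largest residual (the macroscopic corner)
  idx <- which(keep & !is.na(curv) & curv > 0)
  loc_max <- idx[vapply(idx, function(i)
    i > 1 && i < length(curv) &&
      isTRUE(curv[i] >= curv[i - 1]) && isTRUE(curv[i] >= curv[i + 1]),
    logical(1))]
  if (length(loc_max) > 0) return(lambdas[loc_max[which.max(rho[loc_max])]])
  cand <- which(keep & !is.na(curv))
  if (length(cand) == 0) cand <- which(!is.na(curv))
  lambdas[cand[which.max(curv[cand])]]
}

# Map a pixel-raster mask onto a vector-field grid: a node belongs to the
# mask iff its center pixel is labeled (no partial-area weighting).
mask_on_grid <- function(field, mask) {
  if (is.matrix(mask) && identical(dim(mask), dim(field$vx)))
    return(mask != 0)
  if (!inherits(mask, "label_mask"))
    stop("mask must be a label_mask or a node-aligned matrix")
  px <- attr(mask, "pixel_size")
  co <- field_coords(field)
  i <- round(co$y / px) + 1
  j <- round(co$x / px) + 1
  inside <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  out <- matrix(FALSE, nrow(field$vx), ncol(field$vx))
  out[inside] <- mask[cbind(i[inside], j[inside])] != 0
  out
}

#' Mean traction magnitude
#'
#' Mean of `|T|` over the nodes inside the mask (all nodes when no mask is
#' given) — the per-cell summary statistic of a traction experiment.
#'
#' @param traction a [vector_field()] in Pa.
#' @param mask optional [label_mask()] (pixel raster) or node-aligned
#'   logical/integer matrix.
#' @return scalar mean traction in Pa.
#' @export
mean_traction <- function(traction, mask = NULL) {
  stopifnot(inherits(traction, "vector_field"))
  mag <- sqrt(traction$vx^2 + traction$vy^2)
  if (is.null(mask)) return(mean(mag))
  sel <- mask_on_grid(traction, mask)
  if (!any(sel)) stop("mask does not overlap the traction grid")
  mean(mag[sel])
}
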