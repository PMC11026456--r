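# Boussinesq half-space elasticity: forward problem (traction -> surface
# displacement) by spectral convolution or direct real-space summation.

# DFT sample frequencies (cycles per um) for n samples spaced d apart.
fft_freq <- function(n, d) {
  c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * d)
}

# Fourier-domain Boussinesq tensor G(k) such that u_hat = G %*% t_hat:
# G(k) = 2 (1 + nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky ;
#                                 -nu kx ky,  (1-nu) k^2 + nu kx^2 ]
# Returns matrices gxx, gxy, gyy over the (kx, ky) grid; the k = 0 entry is 0.
boussinesq_greens_ft <- function(nx, ny, spacing, E, nu) {
  kx <- 2 * pi * fft_freq(nx, spacing)
  ky <- 2 * pi * fft_freq(ny, spacing)
  KX <- matrix(rep(kx, each = ny), ny, nx)
  KY <- matrix(rep(ky, times = nx), ny, nx)
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  pref <- 2 * (1 + nu) / (E * pmax(K, .Machine$double.xmin)^3)
  gxx <- pref * ((1 - nu) * K2 + nu * KY^2)
  gyy <- pref * ((1 - nu) * K2 + nu * KX^2)
  gxy <- -pref * nu * KX * KY
  gxx[1, 1] <- 0; gyy[1, 1] <- 0; gxy[1, 1] <- 0
  list(gxx = gxx, gxy = gxy, gyy = gyy)
}

fft2 <- function(m) fft(m)
ifft2 <- function(m) fft(m, inverse = TRUE) / length(m)

#' Surface displacement of an elastic half-space under a traction field
#'
#' Solves the forward Boussinesq problem: given a tangential traction field on
#' the surface of a linear-elastic half-space, compute the in-plane surface
#' displacement. The `spectral` method convolves with the half-space Green's
#' function in the Fourier domain (zero-padded by one full field size to
#' suppress periodic wrap-around); `direct_sum` performs explicit pairwise
#' real-space summation with the point-force kernel and serves as an
#' independent oracle for the spectral path.
#'
#' @param traction a [vector_field()] with units `"Pa"`.
#' @param substrate a [substrate_model()].
#' @param method `"spectral"` (fast) or `"direct_sum"` (oracle).
#' @param pad logical; zero-pad the spectral solve by one field size
#'   (default `TRUE`). Ignored for `direct_sum`.
#' @param support_tol for `direct_sum`, sources with `|T|` below
#'   `support_tol * max|T|` are skipped.
#' @return a [vector_field()] with units `"um"` on the traction grid.
#' @export
forward_displacement <- function(traction, substrate,
                                 method = c("spectral", "direct_sum"),
                                 pad = TRUE, support_tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(traction, "vector_field"), inherits(substrate, "substrate_model"))
  if (traction$units != "Pa") stop("traction field must have units 'Pa'")
  ny <- nrow(traction$vx); nx <- ncol(traction$vx)
  if (ny < 2 || nx < 2) stop("grid needs at least 2 points per axis")
  if (any(!is.finite(traction$vx)) || any(!is.finite(traction$vy)))
    stop("traction components must be finite")
  E <- substrate$youngs_modulus
  nu <- substrate$poisson_ratio
  h <- traction$spacing
  if (method == "direct_sum") {
    res <- boussinesq_direct_cpp(traction$vx, traction$vy, h, E, nu,
                                 support_tol, 16L)
    return(vector_field(res$ux, res$uy, spacing = h, origin = traction$origin,
                        units = "um"))
  }
  if (pad) { py <- ny; px <- nx } else { py <- 0; px <- 0 }
  TX <- matrix(0, ny + py, nx + px); TY <- matrix(0, ny + py, nx + px)
  TX[seq_len(ny), seq_len(nx)] <- traction$vx
  TY[seq_len(ny), seq_len(nx)] <- traction$vy
  G <- boussinesq_greens_ft(nx + px, ny + py, h, E, nu)
  txh <- fft2(TX); tyh <- fft2(TY)
  ux <- Re(ifft2(G$gxx * txh + G$gxy * tyh))
  uy <- Re(ifft2(G$gxy * txh + G$gyy * tyh))
  vector_field(ux[seq_len(ny), seq_len(nx)], uy[seq_len(ny), seq_len(nx)],
               spacing = h, origin = traction$origin, units = "um")
}

#' Traction-field specification for the synthetic generator
#'
#' Describes a ground-truth traction pattern as a list of Gaussian force
#' patches. Each patch is `list(center = c(x, y) um, peak = Pa, width = um,
#' orientation = degrees, anisotropy >= 1)`: a traction patch of peak
#' magnitude `peak` pointing along `orientation`, with Gaussian envelope of
#' s.d. `width` elongated by `anisotropy` along its axis.
#'
#' @param patches list of patch descriptors (see above).
#' @param net_force_balanced if `TRUE`, the rendered field is corrected to
#'   integrate to the zero vector (the correction is distributed over the
#'   existing patch envelopes so the field stays compactly supported).
#' @return a `traction_spec` object.
#' @export
traction_spec <- function(patches, net_force_balanced = TRUE) {
  for (p in patches) {
    stopifnot(length(p$center) == 2, p$width > 0)
    if (!is.null(p$anisotropy) && p$anisotropy < 1) stop("anisotropy must be >= 1")
  }
  structure(list(patches = patches, net_force_balanced = net_force_balanced),
            class = "traction_spec")
}

#' Two opposing traction patches (a contractile pair)
#'
#' Convenience constructor: two patches of equal peak and width at
#' `center +/- (separation/2)` along `orientation`, pointing toward each
#' other (contractile).
#'
#' @param center pair (x, y) in um.
#' @param separation distance between patch centers in um.
#' @param peak peak traction in Pa.
#' @param width Gaussian s.d. of each patch in um.
#' @param orientation axis of the pair in degrees.
#' @return a [traction_spec()].
#' @export
balanced_patch_pair <- function(center = c(0, 0), separation = 100, peak = 150,
                                width = 25, orientation = 0) {
  th <- orientation * pi / 180
  d <- c(cos(th), sin(th)) * separation / 2
  traction_spec(list(
    list(center = center + d, peak = peak, width = width,
         orientation = orientation + 180, anisotropy = 1),
    list(center = center - d, peak = peak, width = width,
         orientation = orientation, anisotropy = 1)
  ), net_force_balanced = TRUE)
}

#' Render a traction specification on a regular grid
#'
#' @param spec a [traction_spec()].
#' @param n_nodes grid nodes per axis (scalar or `c(nx, ny)`).
#' @param spacing node spacing in um.
#' @param origin physical (x, y) of the first node in um.
#' @return a [vector_field()] with units `"Pa"`.
#' @export
traction_field_from_spec <- function(spec, n_nodes, spacing, origin = c(0, 0)) {
  stopifnot(inherits(spec, "traction_spec"))
  n_nodes <- rep(as.integer(n_nodes), length.out = 2)
  nx <- n_nodes[1]; ny <- n_nodes[2]
  x <- origin[1] + (seq_len(nx) - 1) * spacing
  y <- origin[2] + (seq_len(ny) - 1) * spacing
  X <- matrix(rep(x, each = ny), ny, nx)
  Y <- matrix(rep(y, times = nx), ny, nx)
  tx <- matrix(0, ny, nx); ty <- matrix(0, ny, nx)
  env_sum <- matrix(0, ny, nx)
  for (p in spec$patches) {
    th <- p$orientation * pi / 180
    an <- if (is.null(p$anisotropy)) 1 else p$anisotropy
    sa <- p$width * an; sb <- p$width
    dx <- X - p$center[1]; dy <- Y - p$center[2]
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    env <- exp(-0.5 * ((xr / sa)^2 + (yr / sb)^2))
    tx <- tx + p$peak * env * cos(th)
    ty <- ty + p$peak * env * sin(th)
    env_sum <- env_sum + env
  }
  if (isTRUE(spec$net_force_balanced)) {
    tot <- sum(env_sum)
    if (tot > 0) {
      net_x <- sum(tx); net_y <- sum(ty)
      tx <- tx - net_x * env_sum / tot
      ty <- ty - net_y * env_sum / tot
    }
  }
  vector_field(tx, ty, spacing = spacing, origin = origin, units = "Pa")
}

#' Net force of a traction field
#' @param traction a [vector_field()] in Pa.
#' @return length-2 numeric, integral of (Tx, Ty) in Pa um^2.
#' @export
net_force <- function(traction) {
  dA <- traction$spacing^2
  c(sum(traction$vx), sum(traction$vy)) * dA
}
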