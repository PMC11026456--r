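# First moment (force dipole) of a masked traction field and its anisotropy.

#' Traction dipole moment matrix
#'
#' First moment of the masked traction field,
#' `M_ij = sum_nodes (x_i - o_i) T_j dA` with `dA` the grid-cell area,
#' symmetrized as `(M + M^T)/2` before diagonalization (the raw discrete
#' first moment need not be symmetric). The origin `o` defaults to the
#' traction-weighted center, which makes the moment robust to slight force
#' imbalance.
#'
#' @param traction a [vector_field()] in Pa.
#' @param mask [label_mask()], node-aligned matrix, or `NULL` for all nodes.
#' @param origin `"traction_weighted_center"`, `"mask_centroid"`, or a
#'   numeric (x, y) pair in um.
#' @return a `dipole_result` list: `matrix` (symmetrized, Pa um^3),
#'   `raw_matrix`, `origin_um`, `n_nodes`; complete it with
#'   [dipole_anisotropy()].
#' @export
dipole_matrix <- function(traction, mask = NULL,
                          origin = c("traction_weighted_center", "mask_centroid")) {
  stopifnot(inherits(traction, "vector_field"))
  if (traction$units != "Pa") stop("expected a traction field in Pa")
  sel <- if (is.null(mask)) matrix(TRUE, nrow(traction$vx), ncol(traction$vx))
         else mask_on_grid(traction, mask)
  if (!any(sel)) stop("mask does not overlap the traction grid")
  if (any(!is.finite(traction$vx[sel])) || any(!is.finite(traction$vy[sel])))
    stop("non-finite traction values inside the mask")
  co <- field_coords(traction)
  x <- co$x[sel]; y <- co$y[sel]
  tx <- traction$vx[sel]; ty <- traction$vy[sel]
  dA <- traction$spacing^2
  if (is.numeric(origin)) {
    o <- origin
  } else {
    origin <- match.arg(origin)
    o <- if (origin == "mask_centroid") c(mean(x), mean(y)) else {
      wgt <- sqrt(tx^2 + ty^2)
      if (sum(wgt) == 0) c(mean(x), mean(y))
      else c(sum(x * wgt), sum(y * wgt)) / sum(wgt)
    }
  }
  M <- matrix(c(sum((x - o[1]) * tx), sum((x - o[1]) * ty),
                sum((y - o[2]) * tx), sum((y - o[2]) * ty)),
              2, 2, byrow = TRUE) * dA
  structure(list(matrix = (M + t(M)) / 2, raw_matrix = M, origin_um = o,
                 n_nodes = sum(sel)),
            class = "dipole_result")
}

#' Dipole eigen-decomposition and anisotropy ratio
#'
#' Diagonalizes the symmetrized dipole matrix; eigenvalues are ordered by
#' magnitude (major, minor) and the anisotropy is `Mdelta =
#' |lambda_major| / |lambda_minor| >= 1`. For contractile fields both
#' eigenvalues are negative. When the minor magnitude is below
#' `eps * |major|` the ratio is capped at `1/eps` and flagged degenerate; a
#' zero matrix yields `Mdelta = NA` with a flag.
#'
#' @param result a `dipole_result` from [dipole_matrix()].
#' @param eps degeneracy threshold (default 1e-6).
#' @return the completed `dipole_result` with `eigenvalues`, `eigenvectors`
#'   (columns, major first), `anisotropy` (Mdelta) and `flags`.
#' @export
dipole_anisotropy <- function(result, eps = 1e-6) {
  stopifnot(inherits(result, "dipole_result"))
  M <- result$matrix
  flags <- character(0)
  if (all(M == 0)) {
    result$eigenvalues <- c(0, 0)
    result$eigenvectors <- diag(2)
    result$anisotropy <- NA_real_
    result$flags <- "zero_matrix"
    return(result)
  }
  e <- eigen(M, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  lam <- e$values[ord]
  vec <- e$vectors[, ord, drop = FALSE]
  if (abs(lam[2]) < eps * abs(lam[1])) {
    md <- 1 / eps
    flags <- c(flags, "degenerate_minor")
  } else md <- abs(lam[1]) / abs(lam[2])
  result$eigenvalues <- lam
  result$eigenvectors <- vec
  result$anisotropy <- md
  result$flags <- flags
  result
}

#' @export
print.dipole_result <- function(x, ...) {
  cat("dipole_result\n  M (Pa um^3):\n")
  print(signif(x$matrix, 4))
  if (!is.null(x$anisotropy))
    cat(sprintf("  eigenvalues: %.4g, %.4g  Mdelta = %.4g%s\n",
                x$eigenvalues[1], x$eigenvalues[2], x$anisotropy,
                if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
                else ""))
  invisible(x)
}

#' Dipole analysis in one step
#' @inheritParams dipole_matrix
#' @param eps degeneracy threshold passed to [dipole_anisotropy()].
#' @return a completed `dipole_result`.
#' @export
dipole_analysis <- function(traction, mask = NULL,
                            origin = c("traction_weighted_center", "mask_centroid"),
                            eps = 1e-6) {
  dipole_anisotropy(dipole_matrix(traction, mask, origin), eps = eps)
}
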