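# Single-cell signature scoring: normalization, graph-diffusion smoothing,
# percentile classification and group contrasts.

#' Library-size normalization with log transform
#'
#' Scales each cell to the median library size and applies `log1p` — the
#' standard preprocessing before graph-diffusion smoothing and signature
#' scoring.
#'
#' @param matrix an [expression_matrix()] (state `"raw"`).
#' @param log1p apply `log(1 + x)` after scaling.
#' @return an [expression_matrix()] with state `"normalized"`.
#' @export
normalize_expression <- function(matrix, log1p = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  lib <- colSums(matrix)
  if (any(lib == 0)) stop("cell(s) with zero total counts")
  vals <- sweep(unclass(matrix), 2, lib / median(lib), "/")
  if (log1p) vals <- log1p(vals)
  out <- expression_matrix(vals, state = "normalized")
  attr(out, "truth") <- attr(matrix, "truth")
  out
}

# Doubly stochastic smoothing operator: symmetric adaptive-bandwidth kNN
# affinity, Sinkhorn-scaled so rows AND columns sum to one (row-stochastic
# diffusion that also conserves per-gene total mass).
diffusion_operator <- function(values, k_neighbors, n_pcs = 20) {
  n <- ncol(values)
  pcs <- stats::prcomp(t(values), center = TRUE, scale. = FALSE,
                       rank. = min(n_pcs, n - 1, nrow(values)))$x
  d2 <- as.matrix(stats::dist(pcs))^2
  sigma <- apply(d2, 1, function(r) sqrt(sort(r)[k_neighbors + 1]))
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
  W <- exp(-d2 / outer(sigma, sigma))
  # keep k nearest per row (plus self), then symmetrize by union
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    keep[i, order(d2[i, ])[seq_len(k_neighbors + 1)]] <- TRUE
  keep <- keep | t(keep)
  W[!keep] <- 0
  W <- Matrix::Matrix(W, sparse = TRUE)
  # Sinkhorn: alternating row/column normalization converges to a doubly
  # stochastic matrix for symmetric W with positive diagonal; the final
  # symmetrization restores exact symmetry without breaking the sums
  for (it in 1:500) {
    W <- W / Matrix::rowSums(W)
    W <- Matrix::t(Matrix::t(W) / Matrix::colSums(W))
    dev <- max(abs(Matrix::rowSums(W) - 1), abs(Matrix::colSums(W) - 1))
    if (dev < 1e-12) break
  }
  (W + Matrix::t(W)) / 2
}

#' Graph-diffusion smoothing of an expression matrix
#'
#' A declared, simplified stand-in for kernel-based imputation: cells are
#' embedded on leading principal components, a symmetric adaptive-bandwidth
#' k-nearest-neighbor affinity is Sinkhorn-normalized to a doubly stochastic
#' transition matrix `P`, and expression is diffused `t` steps
#' (`X <- X P^t` over cells). `t = 0` returns the input unchanged. Because
#' `P` is doubly stochastic, each step preserves the per-gene total across
#' cells exactly.
#'
#' @param matrix an [expression_matrix()]; raw input is normalized first
#'   when `normalize = TRUE`.
#' @param k_neighbors neighbors per cell (must be < number of cells).
#' @param diffusion_steps number of diffusion steps `t` (>= 0).
#' @param n_pcs principal components for the cell embedding.
#' @param normalize apply [normalize_expression()] to raw input.
#' @return an [expression_matrix()] with state `"smoothed"` (state
#'   unchanged when `t = 0`).
#' @export
smooth_expression <- function(matrix, k_neighbors = 15, diffusion_steps = 2,
                              n_pcs = 20, normalize = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  n <- ncol(matrix)
  if (k_neighbors >= n) stop("k_neighbors must be < number of cells")
  if (attr(matrix, "state") == "raw") {
    if (!normalize) stop("input is raw; normalize it first or set normalize = TRUE")
    matrix <- normalize_expression(matrix)
  }
  if (diffusion_steps == 0) return(matrix)
  P <- diffusion_operator(unclass(matrix), k_neighbors, n_pcs)
  vals <- unclass(matrix); attributes(vals) <- list(dim = dim(matrix),
                                                    dimnames = dimnames(matrix))
  for (s in seq_len(diffusion_steps))
    vals <- as.matrix(vals %*% P)
  out <- expression_matrix(pmax(vals, 0), state = "smoothed")
  attr(out, "truth") <- attr(matrix, "truth")
  out
}

#' Per-cell signature score
#'
#' Arithmetic mean of the listed genes' expression per cell.
#'
#' @param matrix an [expression_matrix()].
#' @param genes gene identifiers; all must be present.
#' @return named numeric vector of per-cell scores.
#' @export
signature_score <- function(matrix, genes = lgr5_signature_genes()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (length(genes) == 0) stop("empty gene list")
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  colMeans(matrix[genes, , drop = FALSE])
}

#' Percentile classification of signature scores
#'
#' The threshold is the given percentile of the score distribution
#' (linear-interpolation definition, R quantile type 7); cells strictly
#' above the threshold are labeled `LGR5+`. With all-equal scores no cell
#' is labeled and the result is flagged degenerate. A bimodality flag
#' (Hartigan-style dip of the score histogram) surfaces datasets where the
#' two populations cannot be distinguished, instead of silently excluding
#' them.
#'
#' @param scores per-cell numeric scores (>= 4 cells).
#' @param percentile threshold percentile (default 75).
#' @return a `signature_result` list: `scores`, `threshold`, `labels`
#'   (factor `LGR5+`/`LGR5-`), `percentile`, `flags`.
#' @export
classify_lgr5 <- function(scores, percentile = 75) {
  if (length(scores) < 4) stop("need >= 4 cells")
  thr <- as.numeric(quantile(scores, percentile / 100, type = 7, names = FALSE))
  labels <- factor(ifelse(scores > thr, "LGR5+", "LGR5-"),
                   levels = c("LGR5+", "LGR5-"))
  flags <- character(0)
  if (length(unique(scores)) == 1) flags <- c(flags, "degenerate_scores")
  # crude bimodality check: deepest interior valley of a smoothed histogram
  # relative to its flanking peaks
  h <- hist(scores, breaks = "FD", plot = FALSE)$counts
  if (length(h) >= 5) {
    sm <- stats::filter(h, rep(1 / 3, 3), sides = 2)
    sm <- as.numeric(sm[!is.na(sm)])
    if (length(sm) >= 3) {
      left_max <- cummax(sm)
      right_max <- rev(cummax(rev(sm)))
      dip <- max(pmin(left_max, right_max) - sm)
      if (dip < 0.05 * max(sm)) flags <- c(flags, "unimodal_scores")
    }
  }
  structure(list(scores = scores, threshold = thr, labels = labels,
                 percentile = percentile, flags = flags),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d cells, threshold %.4g (p%g), %d LGR5+ (%.1f%%)%s\n",
              length(x$scores), x$threshold, x$percentile,
              sum(x$labels == "LGR5+"),
              100 * mean(x$labels == "LGR5+"),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Mean expression per gene and signature group
#'
#' @param matrix an [expression_matrix()].
#' @param labels a `signature_result` (or factor with levels `LGR5+`,
#'   `LGR5-`) aligned with the matrix columns.
#' @param genes genes to report (default the ERM genes).
#' @return data frame: gene, mean_lgr5_pos, mean_lgr5_neg, difference
#'   (pos - neg), ratio (pos / neg).
#' @export
group_mean_expression <- function(matrix, labels, genes = erm_genes()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  lab <- if (inherits(labels, "signature_result")) labels$labels else labels
  if (length(lab) != ncol(matrix)) stop("labels do not match matrix columns")
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  pos <- lab == "LGR5+"; neg <- lab == "LGR5-"
  if (!any(pos) || !any(neg)) stop("both groups must be non-empty")
  mp <- rowMeans(matrix[genes, pos, drop = FALSE])
  mn <- rowMeans(matrix[genes, neg, drop = FALSE])
  data.frame(gene = genes, mean_lgr5_pos = as.numeric(mp),
             mean_lgr5_neg = as.numeric(mn),
             difference = as.numeric(mp - mn),
             ratio = as.numeric(mp / mn))
}
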