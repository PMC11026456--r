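# Synthetic contour populations, centroid tracks and expression matrices.

#' Synthetic contour population with analytic ground truth
#'
#' Families: `"circle"` (porosity exactly 1), `"ellipse"` (axis ratio drawn in
#' 1.2-2.5, porosity 1), `"notched"` (circle with a smooth radial notch, so
#' the convex hull strictly exceeds the contour area and porosity > 1).
#' Truth values come from dense polygonal evaluation at `truth_n` vertices.
#'
#' @param n number of contours (>= 1).
#' @param family shape family.
#' @param size_range area range in um^2 (uniform draw).
#' @param n_vertices vertices per returned contour.
#' @param truth_n vertices for the dense ground-truth evaluation.
#' @param seed integer seed.
#' @return a [contour_set()]; `$truth` has columns id, area_um2,
#'   perimeter_um, porosity.
#' @export
gen_contours <- function(n, family = c("circle", "ellipse", "notched"),
                         size_range = c(100, 400), n_vertices = 128,
                         truth_n = 4096, seed = 1) {
  family <- match.arg(family)
  if (n < 1) stop("n must be >= 1")
  if (diff(range(size_range)) < 0 || any(size_range <= 0))
    stop("degenerate size_range")
  set.seed(seed)
  cts <- vector("list", n)
  tr <- data.frame(id = seq_len(n), area_um2 = NA_real_,
                   perimeter_um = NA_real_, porosity = NA_real_)
  for (i in seq_len(n)) {
    area <- runif(1, size_range[1], size_range[2])
    rot <- runif(1, 0, 360)
    make <- switch(family,
      circle = {
        r <- sqrt(area / pi)
        function(nv) polygon_circle(c(0, 0), r, nv)
      },
      ellipse = {
        q <- runif(1, 1.2, 2.5)            # axis ratio a/b
        b <- sqrt(area / (pi * q)); a <- q * b
        function(nv) polygon_ellipse(c(0, 0), a, b, rot, nv)
      },
      notched = {
        r0 <- sqrt(area / pi)
        # narrow, deep notches dent the area but barely the hull, spreading
        # porosity across the conventional 1.05 quality gate
        depth <- runif(1, 0.4, 0.85)
        w <- runif(1, 0.08, 0.3)
        th0 <- runif(1, 0, 2 * pi)
        function(nv) polygon_star(c(0, 0), function(th) {
          d <- atan2(sin(th - th0), cos(th - th0))
          r0 * (1 - depth * exp(-0.5 * (d / w)^2))
        }, nv)
      })
    dense <- contour(make(truth_n), id = i)
    cts[[i]] <- contour(make(n_vertices), id = i)
    tr$area_um2[i] <- contour_area(dense)
    tr$perimeter_um[i] <- contour_perimeter(dense)
    tr$porosity[i] <- contour_hull_area(dense) / contour_area(dense)
  }
  contour_set(cts, truth = tr)
}

#' Synthetic centroid tracks with known velocities
#'
#' Ground-truth velocity is accumulated path length over total elapsed time;
#' for `linear` motion with step `s` per frame it is exactly `s / interval`.
#'
#' @param n_objects number of objects.
#' @param motion `"stationary"`, `"linear"` or `"random_walk"`.
#' @param step displacement per frame in um (>= 0).
#' @param n_frames number of frames (>= 2).
#' @param frame_interval time between frames in minutes.
#' @param spacing distance between object starting positions in um.
#' @param seed integer seed.
#' @return list with `centroids` (data frame: frame, object_id, x_um, y_um)
#'   and `truth` (data frame: object_id, velocity_um_min).
#' @export
gen_tracks <- function(n_objects = 5, motion = c("stationary", "linear", "random_walk"),
                       step = 5, n_frames = 10, frame_interval = 20,
                       spacing = 100, seed = 1) {
  motion <- match.arg(motion)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (step < 0) stop("step must be >= 0")
  set.seed(seed)
  rows <- list(); tru <- numeric(n_objects)
  for (o in seq_len(n_objects)) {
    start <- c((o - 1) %% 10, (o - 1) %/% 10) * spacing
    if (motion == "linear") {
      th <- runif(1, 0, 2 * pi)
      dxy <- matrix(rep(step * c(cos(th), sin(th)), n_frames - 1),
                    ncol = 2, byrow = TRUE)
    } else if (motion == "random_walk") {
      th <- runif(n_frames - 1, 0, 2 * pi)
      dxy <- step * cbind(cos(th), sin(th))
    } else {
      dxy <- matrix(0, n_frames - 1, 2)
    }
    xy <- rbind(start, cbind(start[1] + cumsum(dxy[, 1]),
                             start[2] + cumsum(dxy[, 2])))
    rows[[o]] <- data.frame(frame = seq_len(n_frames), object_id = o,
                            x_um = xy[, 1], y_um = xy[, 2])
    tru[o] <- sum(sqrt(rowSums(dxy^2))) / ((n_frames - 1) * frame_interval)
  }
  list(centroids = do.call(rbind, rows),
       truth = data.frame(object_id = seq_len(n_objects),
                          velocity_um_min = tru),
       frame_interval = frame_interval)
}

#' Signature and marker gene sets
#'
#' The five-gene intestinal stemness signature used for LGR5 classification,
#' and the three ERM (Ezrin/Radixin/Moesin) membrane-to-cortex attachment
#' genes.
#' @return character vector of gene symbols.
#' @export
lgr5_signature_genes <- function() c("BCL11B", "AXIN2", "LGR5", "ASCL2", "LRIG1")

#' @rdname lgr5_signature_genes
#' @export
erm_genes <- function() c("EZR", "RDX", "MSN")

#' Synthetic single-cell expression matrix with a planted LGR5-high subset
#'
#' Counts follow a negative-binomial model with log-normal per-cell size
#' factors. A planted fraction of cells has the five signature genes elevated
#' `signature_effect`-fold; in those cells EZR is reduced
#' `erm_anticorrelation`-fold (RDX and MSN at square-root strength, matching
#' the weaker, patient-subset anticorrelation of Radixin/Moesin). `noise` is
#' the NB dispersion (variance = mu + noise * mu^2); `noise = 0` returns the
#' deterministic expected counts.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (>= 8: the 5 signature genes + EZR/RDX/MSN).
#' @param lgr5_high_fraction planted LGR5-high fraction in (0, 1).
#' @param erm_anticorrelation fold-reduction of EZR in planted-high cells
#'   (1 = no effect).
#' @param noise NB dispersion (>= 0).
#' @param seed integer seed.
#' @param signature_effect fold-elevation of signature genes in planted-high
#'   cells.
#' @param size_factor_sd s.d. of log-normal per-cell size factors.
#' @return an [expression_matrix()] (raw counts) with attribute `truth`
#'   (planted-high cell ids and the generating parameters).
#' @export
gen_expression <- function(n_cells = 2000, n_genes = 60,
                           lgr5_high_fraction = 0.25,
                           erm_anticorrelation = 2, noise = 0.3, seed = 1,
                           signature_effect = 3, size_factor_sd = 0.2) {
  sig <- lgr5_signature_genes(); erm <- erm_genes()
  need <- c(sig, erm)
  if (n_genes < length(need))
    stop("n_genes must be >= ", length(need), " to hold ", paste(need, collapse = ", "))
  if (lgr5_high_fraction <= 0 || lgr5_high_fraction >= 1)
    stop("lgr5_high_fraction must be in (0, 1)")
  if (noise < 0) stop("noise (NB dispersion) must be >= 0")
  set.seed(seed)
  genes <- c(need, sprintf("GENE%03d", seq_len(n_genes - length(need))))[seq_len(n_genes)]
  cells <- sprintf("cell%04d", seq_len(n_cells))
  base <- stats::setNames(rlnorm(n_genes, log(2), 0.8), genes)
  base[sig] <- 2; base["EZR"] <- 5; base["RDX"] <- 2; base["MSN"] <- 1.5
  high <- sort(sample(n_cells, max(1L, floor(lgr5_high_fraction * n_cells))))
  is_high <- seq_len(n_cells) %in% high
  sf <- if (size_factor_sd > 0) rlnorm(n_cells, 0, size_factor_sd) else rep(1, n_cells)
  mu <- matrix(base, n_genes, n_cells, dimnames = list(genes, cells)) *
    matrix(sf, n_genes, n_cells, byrow = TRUE)
  mu[sig, is_high] <- mu[sig, is_high] * signature_effect
  mu["EZR", is_high] <- mu["EZR", is_high] / erm_anticorrelation
  mu[c("RDX", "MSN"), is_high] <- mu[c("RDX", "MSN"), is_high] / sqrt(erm_anticorrelation)
  counts <- if (noise > 0)
    matrix(rnbinom(length(mu), size = 1 / noise, mu = mu), n_genes, n_cells)
  else mu
  dimnames(counts) <- list(genes, cells)
  out <- expression_matrix(counts, state = "raw")
  attr(out, "truth") <- list(high_cells = cells[is_high],
                             params = list(lgr5_high_fraction = lgr5_high_fraction,
                                           erm_anticorrelation = erm_anticorrelation,
                                           noise = noise,
                                           signature_effect = signature_effect))
  out
}
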