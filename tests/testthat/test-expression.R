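# Normalization, diffusion smoothing, signature scoring, classification and
# group contrasts.

test_that("smooth_expression: identity at t = 0 and argument checks", {
  em <- gen_expression(n_cells = 60, n_genes = 20, seed = 1)
  nm <- normalize_expression(em)
  s0 <- smooth_expression(nm, k_neighbors = 5, diffusion_steps = 0)
  expect_equal(unclass(s0)[, ], unclass(nm)[, ])
  expect_error(smooth_expression(nm, k_neighbors = 60), "k_neighbors")
  expect_error(smooth_expression(em, normalize = FALSE), "raw")
})

test_that("diffusion preserves per-gene mass and mixes disconnected blocks", {
  # two well-separated blocks of near-identical cells
  set.seed(5)
  g <- 12; n <- 24
  block1 <- matrix(rep(c(10, 2, 5, 1, 8, 3, 2, 6, 4, 9, 1, 7), n / 2), g) +
    matrix(rnorm(g * n / 2, 0, 0.05), g)
  block2 <- matrix(rep(c(1, 9, 2, 8, 1, 6, 7, 2, 9, 1, 8, 2), n / 2), g) +
    matrix(rnorm(g * n / 2, 0, 0.05), g)
  vals <- pmax(cbind(block1, block2), 0)
  dimnames(vals) <- list(sprintf("g%02d", 1:g), sprintf("c%02d", 1:n))
  em <- expression_matrix(vals, state = "normalized")
  sm <- smooth_expression(em, k_neighbors = 5, diffusion_steps = 40,
                          n_pcs = 5, normalize = FALSE)
  # mass preservation per gene
  expect_lt(max(abs(rowSums(sm) - rowSums(em)) / rowSums(em)), 1e-6)
  # within-block convergence toward the block mean
  for (cols in list(1:(n / 2), (n / 2 + 1):n)) {
    bm <- rowMeans(vals[, cols])
    before <- max(abs(sweep(vals[, cols], 1, bm)))
    after <- max(abs(sweep(unclass(sm)[, cols], 1, rowMeans(unclass(sm)[, cols]))))
    expect_lt(after, 0.05 * max(before, 1e-9))
  }
  # blocks do not contaminate each other: block means stay distinct
  expect_gt(max(abs(rowMeans(unclass(sm)[, 1:(n / 2)]) -
                    rowMeans(unclass(sm)[, (n / 2 + 1):n]))), 1)
})

test_that("signature_score is the per-cell mean of the listed genes", {
  vals <- matrix(0, 6, 3,
                 dimnames = list(c(lgr5_signature_genes(), "EZR"),
                                 c("a", "b", "c")))
  vals[, 1] <- c(rep(4, 5), 9)
  vals[1, 2] <- 10  # one gene 10, four 0 -> score 2
  em <- expression_matrix(vals, state = "normalized")
  sc <- signature_score(em)
  expect_equal(unname(sc), c(4, 2, 0))
  # permuting gene order changes nothing
  expect_equal(signature_score(em, rev(lgr5_signature_genes())), sc)
  expect_error(signature_score(em, character(0)), "empty")
  expect_error(signature_score(em, c("LGR5", "NOPE")), "NOPE")
})

test_that("classify_lgr5 implements the strict 75th-percentile rule", {
  res <- classify_lgr5(1:100)
  # oracle: count above the interpolated 75th percentile of 1..100
  thr <- quantile(1:100, 0.75, type = 7, names = FALSE)
  expect_equal(sum(res$labels == "LGR5+"), sum((1:100) > thr))
  expect_equal(sum(res$labels == "LGR5+"), 25L)
  # all-equal scores: none labeled, degenerate flag
  deg <- classify_lgr5(rep(3, 10))
  expect_equal(sum(deg$labels == "LGR5+"), 0L)
  expect_true("degenerate_scores" %in% deg$flags)
  # shift invariance
  set.seed(2); x <- rnorm(50)
  expect_equal(classify_lgr5(x)$labels, classify_lgr5(x + 17)$labels)
  # monotone: raising one labeled cell's score keeps its label
  res2 <- classify_lgr5(1:100)
  top <- which(res2$labels == "LGR5+")[1]
  x2 <- as.numeric(1:100); x2[top] <- x2[top] + 50
  expect_equal(classify_lgr5(x2)$labels[top], factor("LGR5+", c("LGR5+", "LGR5-")))
  # cap: never more than ceil(0.25 n) labeled for generic scores
  for (s in 1:5) {
    set.seed(s); y <- rnorm(37)
    expect_lte(sum(classify_lgr5(y)$labels == "LGR5+"), ceiling(0.25 * 37))
  }
  expect_error(classify_lgr5(1:3), ">= 4")
})

test_that("group_mean_expression matches hand arithmetic and planting", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
                 dimnames = list(c("EZR", "RDX"), c("a", "b", "c")))
  em <- expression_matrix(vals, state = "normalized")
  lab <- factor(c("LGR5+", "LGR5-", "LGR5-"), c("LGR5+", "LGR5-"))
  gm <- group_mean_expression(em, lab, c("EZR", "RDX"))
  expect_equal(gm$mean_lgr5_pos, c(1, 2))
  expect_equal(gm$mean_lgr5_neg, c(4, 5))
  expect_equal(gm$difference, c(-3, -3))
  expect_equal(gm$ratio, c(0.25, 0.4))
  expect_error(group_mean_expression(em, factor(rep("LGR5-", 3),
                                                c("LGR5+", "LGR5-")),
                                     genes = c("EZR", "RDX")),
               "non-empty")
  # planted matrix: classification recovers the EZR direction
  em2 <- gen_expression(n_cells = 800, n_genes = 30, erm_anticorrelation = 2,
                        noise = 0.3, seed = 11)
  nm <- normalize_expression(em2)
  res <- classify_lgr5(signature_score(nm))
  gm2 <- group_mean_expression(nm, res)
  expect_lt(gm2$difference[gm2$gene == "EZR"], 0)
})

test_that("noiseless planting at fraction 0.25 is recovered exactly", {
  em <- gen_expression(n_cells = 200, n_genes = 20, lgr5_high_fraction = 0.25,
                       noise = 0, seed = 6)
  res <- classify_lgr5(signature_score(normalize_expression(em)))
  called <- colnames(em)[res$labels == "LGR5+"]
  expect_setequal(called, attr(em, "truth")$high_cells)
})
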