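test_that("window labels follow floor(pos / window_size) as chrom@index", {
  snvs <- make_snvs(3, chrom = c("chr22", "chr7", "chr22"),
                    pos = c(32812345L, 23274960L, 32899999L))
  m <- make_ssm(matrix(1, 4, 3), snvs = snvs)
  wm <- window_aggregate(m)
  expect_setequal(wm$windows$label, c("chr22@328", "chr7@232"))
  # the two chr22 SNVs share window 328
  expect_equal(sum(wm$counts[, "chr22@328"]), 8)

  one <- window_aggregate(m, window_size = 1e9)
  expect_equal(sort(one$windows$label), sort(c("chr22@0", "chr7@0")))
})

test_that("window aggregation conserves totals and partitions SNVs", {
  set.seed(2)
  snvs <- make_snvs(50, chrom = sample(paste0("chr", 1:3), 50, TRUE),
                    pos = sample.int(2e6, 50))
  cnt <- matrix(rpois(20 * 50, 0.7), 20, 50)
  m <- make_ssm(cnt, snvs = snvs)
  wm <- window_aggregate(m, 100000)
  expect_equal(sum(wm$counts), sum(cnt))
  expect_equal(Matrix::rowSums(wm$counts), Matrix::rowSums(m$counts))
  # each SNV maps to exactly one window (sum of member counts = column total)
  lab <- paste0(snvs$chrom, "@", floor(snvs$pos / 1e5))
  for (w in wm$windows$label) {
    expect_equal(as.numeric(Matrix::rowSums(
      m$counts[, lab == w, drop = FALSE])), as.numeric(wm$counts[, w]))
  }
})

test_that("Gaussian k-NN weights have the closed-form kernel values", {
  sp <- make_spots(coords = data.frame(x = c(0, 1, 3), y = c(0, 0, 0)))
  w <- spatial_weights(sp, k = 1, alpha = 1)
  expect_equal(Matrix::diag(w$W), setNames(rep(1, 3), sp$barcode))  # D = 0
  expect_equal(w$W[1, 2], exp(-1 / 2))                      # D = alpha
  expect_equal(w$W[2, 3], exp(-4 / 2))                      # D = 2 alpha
  expect_equal(as.matrix(w$W), t(as.matrix(w$W)))           # union-symmetric
  expect_equal(w$W[1, 3], 0)                                # not neighbors
  expect_error(spatial_weights(sp, k = 3), "smaller")
})

test_that("default bandwidth is the mean k-NN distance and weights decay with distance", {
  set.seed(8)
  sp <- make_spots(coords = data.frame(x = runif(30, 0, 10),
                                       y = runif(30, 0, 10)))
  w <- spatial_weights(sp, k = 4)
  D <- as.matrix(dist(cbind(sp$x, sp$y)))
  knn_mean <- mean(apply(D, 1, function(r) mean(sort(r)[2:5])))
  expect_equal(w$alpha, knn_mean)
  # monotone: for a given spot, nearer neighbors get larger weights
  i <- 1
  nb <- which(w$W[i, ] > 0 & seq_len(30) != i)
  o <- order(D[i, nb])
  expect_true(all(diff(w$W[i, nb][o]) <= 1e-12))
})

test_that("smoothing is the matrix product W x M with its limiting cases", {
  set.seed(4)
  sp <- make_spots(coords = expand.grid(x = 0:4, y = 0:4))
  cnt <- matrix(rpois(25 * 3, 1), 25, 3)
  m <- make_ssm(cnt, spots = sp)
  wm <- window_aggregate(m)
  w <- spatial_weights(sp, k = 3, alpha = 1)

  sm <- smooth_windows(wm, w)
  expect_equal(as.matrix(sm$smoothed),
               as.matrix(w$W) %*% as.matrix(wm$counts),
               ignore_attr = TRUE)                  # dense-product oracle
  expect_true(all(sm$smoothed >= 0))

  # identity weights leave M unchanged
  wid <- structure(list(W = Matrix::Diagonal(25), alpha = 1, k = 0),
                   class = "spatial_weights")
  expect_equal(as.matrix(smooth_windows(wm, wid)$smoothed),
               as.matrix(wm$counts), ignore_attr = TRUE)

  # row-normalized weights preserve a spatially constant column
  m2 <- make_ssm(matrix(2, 25, 1), spots = sp)
  wm2 <- smooth_windows(window_aggregate(m2), w, row_normalize = TRUE)
  expect_equal(as.numeric(wm2$smoothed), rep(2, 25))
})

test_that("a single nonzero spot spreads exactly to its neighborhood", {
  sp <- make_spots(coords = expand.grid(x = 0:3, y = 0:3))
  cnt <- matrix(0, 16, 1); cnt[1, 1] <- 5
  wm <- window_aggregate(make_ssm(cnt, spots = sp))
  w <- spatial_weights(sp, k = 2, alpha = 1)
  sm <- smooth_windows(wm, w)
  expect_equal(as.numeric(sm$smoothed), as.numeric(w$W[, 1] * 5))
})

test_that("window correlation equals a dense masked-product oracle", {
  set.seed(13)
  sp <- make_spots(coords = expand.grid(x = 0:5, y = 0:5))
  cnt <- matrix(rpois(36 * 10, 0.8), 36, 10)
  snvs <- make_snvs(10, pos = (1:10) * 100001L)
  m <- make_ssm(cnt, spots = sp, snvs = snvs)
  wm <- smooth_windows(window_aggregate(m), spatial_weights(sp, k = 3))
  got <- window_correlation(wm, top_fraction = 0.5)
  # oracle: explicit per-column masking then dense crossproduct
  M <- as.matrix(wm$smoothed)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]; nz <- v > 0
    if (sum(nz) < 2) { M[, j] <- 0; next }
    thr <- quantile(v[nz], 0.5, names = FALSE)
    M[v < thr, j] <- 0
  }
  expect_equal(got, t(M) %*% M, ignore_attr = TRUE)
  expect_equal(got, t(got))    # symmetric before row-wise pruning
})

test_that("identical and disjoint windows get maximal and zero correlation", {
  sp <- make_spots(coords = expand.grid(x = 0:3, y = 0:3))
  cnt <- cbind(c(rep(4, 8), rep(0, 8)),
               c(rep(4, 8), rep(0, 8)),
               c(rep(0, 8), rep(4, 8)))
  snvs <- make_snvs(3, pos = c(100001L, 200001L, 300001L))
  wm <- window_aggregate(make_ssm(cnt, spots = sp, snvs = snvs))
  wid <- structure(list(W = Matrix::Diagonal(16), alpha = 1, k = 0),
                   class = "spatial_weights")
  cc <- window_correlation(smooth_windows(wm, wid))
  expect_equal(cc[1, 2], cc[1, 1])   # identical windows: maximal mutual score
  expect_equal(cc[1, 3], 0)          # disjoint support
  # a window with < 2 nonzero spots is zeroed
  cnt2 <- cbind(cnt[, 1], c(3, rep(0, 15)))
  wm2 <- window_aggregate(make_ssm(cnt2, spots = sp,
                                   snvs = make_snvs(2, pos = c(100001L, 200001L))))
  cc2 <- window_correlation(smooth_windows(wm2, wid))
  expect_equal(as.numeric(cc2[, 2]), rep(0, 2))
})

test_that("group graph keeps top partners with Gaussian-decayed rank weights", {
  set.seed(17)
  n <- 12
  corr <- crossprod(matrix(runif(n * n), n))   # symmetric positive scores
  dimnames(corr) <- list(paste0("w", 1:n), paste0("w", 1:n))
  g <- build_group_graph(corr, top_fraction = 0.5, decay_alpha = 0.5)
  el <- igraph::as_data_frame(g)
  # oracle: explicit per-row sort and decay
  for (i in 1:n) {
    s <- corr[i, ]; s[i] <- 0
    cand <- which(s > 0)
    keep <- cand[order(s[cand], decreasing = TRUE)][1:ceiling(length(cand) / 2)]
    rows <- el[el$from == paste0("w", i), ]
    expect_setequal(rows$to, paste0("w", keep))
    r <- 1 - s[keep] / max(s[keep])
    expect_equal(rows$weight[match(paste0("w", keep), rows$to)],
                 unname(exp(-r^2 / 0.5)))
    # the top partner gets the maximal weight 1 in its row
    expect_equal(max(rows$weight), 1)
  }
})

test_that("Leiden recovers obvious community structure", {
  # two disconnected cliques -> exactly 2 groups
  blocks <- function(sizes, w = 1) {
    n <- sum(sizes)
    corr <- matrix(0, n, n)
    ofs <- 0
    for (s in sizes) {
      corr[ofs + 1:s, ofs + 1:s] <- w
      ofs <- ofs + s
    }
    diag(corr) <- 0
    dimnames(corr) <- list(paste0("w", 1:n), paste0("w", 1:n))
    corr
  }
  g2 <- build_group_graph(blocks(c(6, 6)))
  grp2 <- leiden_groups(g2, resolution = 1, seed = 1)
  expect_equal(length(unique(grp2$assignment)), 2L)
  expect_setequal(as.integer(grp2$assignment), c(0L, 1L))

  # planted 4-block graph: exact recovery, ARI = 1
  sizes <- c(5, 6, 7, 8)
  g4 <- build_group_graph(blocks(sizes))
  grp4 <- leiden_groups(g4, resolution = 1, seed = 3)
  truth <- rep(seq_along(sizes), sizes)
  expect_equal(mclust::adjustedRandIndex(truth, grp4$assignment), 1)

  # determinism under a fixed seed
  grp4b <- leiden_groups(g4, resolution = 1, seed = 3)
  expect_identical(grp4$assignment, grp4b$assignment)

  # resolution -> infinity (CPM) yields singletons
  grpS <- leiden_groups(g4, resolution = 100, seed = 1, objective = "CPM")
  expect_equal(length(unique(grpS$assignment)), sum(sizes))
})

test_that("group scores are the UMI-normalized sum over member windows", {
  set.seed(19)
  sp <- make_spots(n = 9, umi = sample(100:400, 9))
  cnt <- matrix(rpois(9 * 4, 1.5), 9, 4)
  snvs <- make_snvs(4, pos = (1:4) * 100001L)
  wm <- window_aggregate(make_ssm(cnt, spots = sp, snvs = snvs))
  asg <- setNames(c(0L, 0L, 1L, 2L), colnames(wm$counts))
  sc <- group_scores(wm, asg)
  # direct-sum oracle
  expect_equal(sc[, "group_0"],
               setNames(log1p((cnt[, 1] + cnt[, 2]) / sp$total_umi),
                        sp$barcode))
  # single-window group equals that window's normalized column
  expect_equal(sc[, "group_1"],
               setNames(log1p(cnt[, 3] / sp$total_umi), sp$barcode))
})

test_that("representative gene picks the unique, none, or best-correlated gene", {
  set.seed(23)
  sp <- make_spots(n = 16)
  snvs <- make_snvs(4, pos = c(100001L, 100501L, 200001L, 300001L))
  snvs$gene <- c("GA", "GA", NA, "GB")
  snvs$genomic_region <- c("exonic", "UTR3", "intergenic", "exonic")
  cnt <- matrix(rpois(16 * 4, 1), 16, 4)
  wm <- window_aggregate(make_ssm(cnt, spots = sp, snvs = snvs))
  rg <- representative_gene(wm)
  expect_equal(unname(rg["chr1@1"]), "GA")   # single-gene window
  expect_true(is.na(rg["chr1@2"]))           # intergenic-only window

  # multi-gene window: the planted correlated gene wins
  snvs2 <- make_snvs(2, pos = c(100001L, 100501L))
  snvs2$gene <- c("GA", "GB")
  snvs2$genomic_region <- "exonic"
  wcnt <- rpois(16, 3)
  wm2 <- window_aggregate(make_ssm(cbind(wcnt, wcnt), spots = sp,
                                   snvs = snvs2))
  expr <- cbind(GA = rpois(16, 2),
                GB = as.numeric(2 * Matrix::rowSums(wm2$counts) + rnorm(16, 0, .1)))
  rownames(expr) <- sp$barcode
  rg2 <- representative_gene(wm2, expr)
  # brute-force correlation oracle over the candidates
  v <- as.numeric(wm2$counts[, 1])
  expect_equal(unname(rg2[1]),
               c("GA", "GB")[which.max(c(cor(expr[, 1], v),
                                         cor(expr[, 2], v)))])
  expect_equal(unname(rg2[1]), "GB")
})
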