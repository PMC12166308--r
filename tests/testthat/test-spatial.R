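test_that("Moran's I is exactly -1 on a rook-adjacency checkerboard", {
  nr <- 10; nc <- 10
  W <- rook_weights(nr, nc)
  grid <- expand.grid(r = 1:nr, c = 1:nc)
  vals <- ifelse((grid$r + grid$c) %% 2 == 0, 1, -1)
  res <- morans_i(vals, W)
  expect_equal(res$I, -1, tolerance = 1e-12)
  expect_equal(res$n, 100L)
})

test_that("Moran's I matches the O(n^2) brute-force oracle on random instances", {
  set.seed(31)
  for (r in 1:5) {
    sp <- make_spots(coords = data.frame(x = runif(50, 0, 20),
                                         y = runif(50, 0, 20)))
    w <- spatial_weights(sp, k = 5)
    vals <- rnorm(50)
    expect_lt(abs(morans_i(vals, w)$I - moran_brute(vals, w$W)), 1e-10)
  }
})

test_that("Moran's I agrees with an independent library implementation", {
  set.seed(32)
  sp <- make_spots(coords = data.frame(x = runif(40, 0, 10),
                                       y = runif(40, 0, 10)))
  w <- spatial_weights(sp, k = 4)
  vals <- rnorm(40)
  # ape::Moran.I row-normalizes its weight matrix internally, so feed the
  # implementation the same row-normalized weights for the comparison
  Wd <- as.matrix(w$W); diag(Wd) <- 0
  Wn <- Wd / rowSums(Wd)
  expect_equal(morans_i(vals, Wn)$I,
               ape::Moran.I(vals, Wd)$observed, tolerance = 1e-10)
})

test_that("Moran's I is invariant under affine transforms and rejects constants", {
  set.seed(33)
  sp <- make_spots(coords = data.frame(x = runif(30), y = runif(30)))
  w <- spatial_weights(sp, k = 3)
  vals <- rnorm(30)
  i0 <- morans_i(vals, w)$I
  expect_equal(morans_i(5 * vals - 2, w)$I, i0, tolerance = 1e-12)
  expect_error(morans_i(rep(1, 30), w), "constant")
})

test_that("margin-to-tumor distances follow the k-NN definition", {
  # margin spot at the center of a 5-spot tumor cross at unit distance
  sp <- data.frame(
    barcode = paste0("s", 1:6),
    x = c(0, 1, -1, 0, 0, 1),
    y = c(0, 0, 0, 1, -1, 1),
    total_umi = 100,
    region = c("margin", rep("tumor", 5)),
    stringsAsFactors = FALSE)
  sp$x[6] <- 0.6; sp$y[6] <- 0.8   # also unit distance
  d <- distance_to_tumor(sp, k = 5)
  expect_equal(d$distance, 1.0)
  # k = 1 is the nearest-tumor distance
  expect_equal(distance_to_tumor(sp, k = 1)$distance, 1.0)
  expect_error(distance_to_tumor(transform(sp, region = "normal")),
               "tumor")
})

test_that("distance computation matches an exhaustive all-pairs sort oracle", {
  set.seed(41)
  n <- 200
  sp <- make_spots(coords = data.frame(x = runif(n, 0, 30),
                                       y = runif(n, 0, 30)),
                   region = sample(c("tumor", "margin", "normal"), n, TRUE))
  got <- distance_to_tumor(sp, k = 5)
  tum <- sp[sp$region == "tumor", ]
  mar <- sp[sp$region == "margin", ]
  for (i in seq_len(nrow(mar))) {
    dd <- sort(sqrt((tum$x - mar$x[i])^2 + (tum$y - mar$y[i])^2))
    expect_equal(got$distance[i], mean(dd[1:5]))
  }
})

test_that("distances are translation- and rotation-invariant", {
  set.seed(43)
  sp <- make_spots(coords = data.frame(x = runif(60, 0, 10),
                                       y = runif(60, 0, 10)),
                   region = rep(c("tumor", "margin"), each = 30))
  d0 <- distance_to_tumor(sp, k = 5)$distance
  th <- 0.7
  rot <- data.frame(x = cos(th) * sp$x - sin(th) * sp$y + 100,
                    y = sin(th) * sp$x + cos(th) * sp$y - 50)
  sp2 <- sp; sp2$x <- rot$x; sp2$y <- rot$y
  expect_equal(distance_to_tumor(sp2, k = 5)$distance, d0,
               tolerance = 1e-10)
})

test_that("the log-log fit recovers a noiseless power law exactly", {
  d <- seq(0.5, 10, length.out = 50)
  burden <- 0.3 * d^(-0.8)
  fit <- burden_distance_fit(burden, d)
  expect_equal(fit$slope, -0.8, tolerance = 1e-10)
  expect_equal(fit$intercept, log(0.3), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n, 50L)
})

test_that("shuffled burden-distance pairs give near-zero R^2 and zeros are dropped", {
  set.seed(51)
  d <- runif(500, 1, 20)
  burden <- 0.3 * d^(-0.8) * rlnorm(500, 0, 0.2)
  shuf <- burden_distance_fit(sample(burden), d)
  expect_lt(shuf$r_squared, 0.05)
  burden[1:17] <- 0
  expect_message(fit <- burden_distance_fit(burden, d), "17")
  expect_equal(fit$n, 483L)
  expect_equal(fit$n_dropped, 17L)
})

test_that("slope-immune correlation follows the textbook formula", {
  x <- c(-0.9, -0.7, -0.5, -0.2, -0.1)
  y <- c(10, 30, 32, 55, 60)
  got <- slope_vs_immune(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  expect_equal(slope_vs_immune(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_error(slope_vs_immune(c(1, 2), c(3, 4)), "3 sections")
})

test_that("signature scoring centers on zero for self-controls and finds planted shifts", {
  set.seed(61)
  n_spots <- 80; n_genes <- 120
  expr <- matrix(rpois(n_spots * n_genes, 5), n_spots, n_genes,
                 dimnames = list(paste0("s", 1:n_spots),
                                 paste0("g", 1:n_genes)))
  # whole universe as signature: control equals signature strata
  s0 <- signature_score(expr, colnames(expr), n_bins = 5, n_ctrl = 200,
                        seed = 1)
  expect_lt(max(abs(s0)), 0.2)

  # plant an up-shifted gene set in the first 40 spots; wide bins keep
  # genuine controls in the signature genes' expression stratum
  sig <- paste0("g", 1:7)
  expr2 <- expr
  expr2[1:40, sig] <- expr2[1:40, sig] + 6
  s1 <- signature_score(expr2, sig, n_bins = 5, seed = 1)
  expect_gt(mean(s1[1:40]) - mean(s1[41:80]), 2)
  # deterministic under a fixed seed
  expect_identical(s1, signature_score(expr2, sig, n_bins = 5, seed = 1))
})

test_that("burden-pathway correlations rank planted relationships correctly", {
  set.seed(71)
  burden <- runif(100)
  ps <- cbind(self = burden,
              anti = -2 * burden + rnorm(100, 0, 0.1),
              noise = rnorm(100))
  out <- burden_pathway_correlation(burden, ps)
  expect_equal(out$r[out$pathway == "self"], 1)
  expect_lt(out$r[out$pathway == "anti"], -0.9)
  expect_lt(abs(out$r[out$pathway == "noise"]), 0.3)
  expect_equal(out$pathway[1], "self")   # sorted by decreasing r
})

test_that("SNV presence concentrated in the tumor yields a strong chi-square association", {
  set.seed(81)
  region <- rep(c("tumor", "margin", "normal"), each = 50)
  presence <- c(rbinom(50, 1, 0.8), rbinom(50, 1, 0.1), rbinom(50, 1, 0.1))
  res <- region_snv_association(presence, region)
  expect_lt(res$p, 1e-6)
  expect_equal(dim(res$table), c(2L, 3L))
})

test_that("GMT reading returns named gene sets", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tCD68\tCD14\tMMP2",
               "setB\tdesc\tMRC1\tCD163"), p)
  sets <- read_gmt(p)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("CD68", "CD14", "MMP2"))
})
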