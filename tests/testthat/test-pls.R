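test_that("connectome vectorization follows row-major lower-triangle order", {
  expect_equal(nrow(edge_index(100)), 4950)
  M <- matrix(0, 3, 3)
  M[2, 1] <- M[1, 2] <- 21
  M[3, 1] <- M[1, 3] <- 31
  M[3, 2] <- M[2, 3] <- 32
  expect_equal(vectorize_connectome(M), c(21, 31, 32))
  # R = 4 distinguishes row-major from column-major enumeration
  M4 <- matrix(0, 4, 4)
  ei <- edge_index(4)
  vals <- as.numeric(ei$i * 10 + ei$j)
  M4[cbind(ei$i, ei$j)] <- vals
  M4 <- M4 + t(M4)
  expect_equal(vectorize_connectome(M4), c(21, 31, 32, 41, 42, 43))

  expect_equal(devectorize_connectome(vectorize_connectome(M4)), M4)
  Mb <- M; Mb[1, 2] <- 99
  expect_error(vectorize_connectome(Mb), "symmetric")
})

test_that("first PLS component equals the normalized cross-covariance", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 6), 20, 6)
    y <- sample(c(-1, 1), 20, replace = TRUE)
    m <- fit_pls_mode(X, y)
    Xc <- sweep(X, 2, colMeans(X))
    w_oracle <- drop(crossprod(Xc, y - mean(y)))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    # same direction up to the sign convention
    expect_lt(min(max(abs(m$x_weights - w_oracle)),
                  max(abs(m$x_weights + w_oracle))), 1e-8)
    expect_equal(sqrt(sum(m$x_weights^2)), 1, tolerance = 1e-12)
    expect_gte(m$mode_corr, 0)
  }
})

test_that("PLS mode agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(50 * 12), 50, 12)
  y <- rbinom(50, 1, 0.4)
  m <- fit_pls_mode(X, y)
  ref <- mixOmics::pls(X, 2 * y - 1, ncomp = 1, scale = FALSE)
  w_ref <- as.numeric(ref$loadings$X[, 1])
  cosang <- abs(sum(m$x_weights * w_ref) /
                  sqrt(sum(m$x_weights^2) * sum(w_ref^2)))
  expect_gt(cosang, 1 - 1e-8)
})

test_that("PLS orientation and degenerate inputs behave as specified", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rbinom(40, 1, 0.5)
  m1 <- fit_pls_mode(X, y)
  m2 <- fit_pls_mode(X, 1 - y)  # label flip
  expect_equal(abs(sum(m1$x_weights * m2$x_weights)), 1, tolerance = 1e-10)
  expect_equal(m1$mode_corr, m2$mode_corr, tolerance = 1e-10)

  # a feature equal to the label dominates the weights
  X2 <- cbind(2 * y - 1, matrix(rnorm(40 * 4), 40, 4))
  m3 <- fit_pls_mode(X2, y)
  expect_equal(which.max(abs(m3$x_weights)), 1L)

  expect_error(fit_pls_mode(X, rep(1, 40)), "both classes")
  expect_error(fit_pls_mode(matrix(0, 40, 3), y), "degenerate")
})

test_that("permutation test handles the extreme case and is reproducible", {
  set.seed(13)
  n <- 200
  y <- rbinom(n, 1, 0.3)
  X <- cbind(5 * (2 * y - 1) + rnorm(n), matrix(rnorm(n * 9), n, 9))
  pt <- permutation_test(X, y, B = 99, seed = 1)
  expect_equal(pt$p_value, 1 / 100)  # observed beats every null draw
  expect_true(all(pt$null_stats >= 0))
  pt2 <- permutation_test(X, y, B = 99, seed = 1)
  expect_identical(pt$null_stats, pt2$null_stats)
  # default iteration count
  expect_equal(formals(permutation_test)$B, 1000)
})

test_that("planted connectivity mode is recovered at n = 2000", {
  co <- generate_cohort(generator_config(n = 2000, seed = 17,
                                         fc_mode_strength = 4))
  edges <- deconfound(co$fc_edges, co$cohort, character())
  pt <- permutation_test(edges, co$cohort$loneliness, B = 199, seed = 2)
  cosang <- abs(sum(pt$mode$x_weights * co$truth$planted_mode))
  expect_gt(cosang, 0.8)
  expect_lt(pt$p_value, 0.05)
})

test_that("network block summary averages edges exactly", {
  at <- tiny_atlas(c("Visual", "Default"), 2)  # 4 regions, 2 networks
  ei <- edge_index(4)
  w <- c(1, 2, 3, 4, 5, 6)  # edges (2,1),(3,1),(3,2),(4,1),(4,2),(4,3)
  blk <- network_block_summary(w, at)
  # brute-force enumeration: regions 1,2 = Visual; 3,4 = Default
  nets <- c(1, 1, 2, 2)
  sums <- matrix(0, 2, 2); cnt <- matrix(0, 2, 2)
  for (e in seq_len(6)) {
    a <- min(nets[ei$i[e]], nets[ei$j[e]]); b <- max(nets[ei$i[e]], nets[ei$j[e]])
    sums[a, b] <- sums[a, b] + w[e]; cnt[a, b] <- cnt[a, b] + 1
  }
  oracle <- sums / cnt
  expect_equal(blk["Visual", "Visual"], oracle[1, 1])
  expect_equal(blk["Visual", "Default"], oracle[1, 2])
  expect_equal(blk["Default", "Default"], oracle[2, 2])
  expect_equal(blk, t(blk))

  # constant weights give constant blocks
  at7 <- load_atlas()
  blk1 <- network_block_summary(rep(1, 4950), at7)
  expect_equal(unname(as.vector(blk1)), rep(1, 49))
})
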