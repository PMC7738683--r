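#' Edge bookkeeping for a vectorized connectome
#'
#' Row-major lower-triangle order: edges enumerate region pairs (i, j) with
#' i > j, i running over rows — for 3 regions the order is (2,1), (3,1),
#' (3,2) in 1-based terms.
#'
#' @param n_regions Number of atlas regions R.
#' @return Tibble with columns `edge`, `i`, `j` (1-based, i > j), of
#'   `R(R-1)/2` rows.
#' @export
edge_index <- function(n_regions) {
  i <- rep(2:n_regions, times = 1:(n_regions - 1))
  j <- unlist(lapply(2:n_regions, function(k) seq_len(k - 1)), use.names = FALSE)
  tibble(edge = seq_along(i), i = i, j = j)
}

#' Vectorize a symmetric coupling matrix to its lower-triangle edges
#'
#' @param M Symmetric R x R matrix (tolerance 1e-8).
#' @return Numeric vector of length `R(R-1)/2` in row-major i > j order.
#' @export
vectorize_connectome <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8) {
    abort("M must be symmetric (tolerance 1e-8)")
  }
  ei <- edge_index(nrow(M))
  M[cbind(ei$i, ei$j)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_connectome()]; the diagonal is set to zero.
#'
#' @param edges Edge vector of length `R(R-1)/2`.
#' @return Symmetric R x R matrix with zero diagonal.
#' @export
devectorize_connectome <- function(edges) {
  E <- length(edges)
  R <- (1 + sqrt(1 + 8 * E)) / 2
  if (R != round(R)) abort("edge vector length is not R(R-1)/2 for integer R")
  R <- as.integer(R)
  M <- matrix(0, R, R)
  ei <- edge_index(R)
  M[cbind(ei$i, ei$j)] <- edges
  M[cbind(ei$j, ei$i)] <- edges
  M
}

# center X columns and code labels as centered +/-1
pls_prepare <- function(X, y) {
  X <- as.matrix(X)
  yv <- as.numeric(y)
  if (all(yv %in% c(0, 1))) yv <- 2 * yv - 1
  if (!all(yv %in% c(-1, 1))) abort("y must be binary (0/1 or -1/+1)")
  if (length(unique(yv)) < 2) abort("y must contain both classes")
  if (length(yv) != nrow(X)) abort("X and y have different lengths")
  list(Xc = sweep(X, 2, colMeans(X)), yc = yv - mean(yv))
}

#' Fit the dominant partial-least-squares connectome mode
#'
#' Extracts the first PLS component linking edge features to the binary
#' loneliness label (coded +1 lonely / -1 non-lonely, then centered). With a
#' univariate target, the first component's feature weights are exactly the
#' normalized feature-by-label cross-covariance `normalize(t(X) %*% y)`; the
#' sign is chosen so the participant scores correlate positively with the
#' label. Components beyond the first (via X deflation) are available but the
#' package only validates and reports mode 1.
#'
#' @param X Numeric matrix (participants x edges), already deconfounded and
#'   standardized upstream.
#' @param y Binary labels.
#' @param k Number of components (default 1).
#' @return List of class `lb_pls_mode`: `x_weights` (unit norm, first
#'   component), `scores`, `mode_corr` (Pearson correlation of scores with the
#'   label), `k`, `weights_all` (edges x k).
#' @export
fit_pls_mode <- function(X, y, k = 1) {
  pr <- pls_prepare(X, y)
  Xd <- pr$Xc
  W <- matrix(NA_real_, ncol(Xd), k)
  for (comp in seq_len(k)) {
    w <- drop(crossprod(Xd, pr$yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) abort("degenerate mode: zero cross-covariance between X and y")
    w <- w / nw
    t_sc <- drop(Xd %*% w)
    W[, comp] <- w
    if (comp < k) {
      pload <- drop(crossprod(Xd, t_sc)) / sum(t_sc^2)
      Xd <- Xd - tcrossprod(t_sc, pload)
    }
  }
  scores <- drop(pr$Xc %*% W[, 1])
  rho <- cor(scores, pr$yc)
  if (rho < 0) {  # orientation convention: scores align with loneliness
    W <- -W
    scores <- -scores
    rho <- -rho
  }
  structure(list(x_weights = W[, 1], scores = scores, mode_corr = rho,
                 k = k, weights_all = W, n = nrow(pr$Xc)),
            class = "lb_pls_mode")
}

#' Label-permutation test for the dominant PLS mode
#'
#' Holds the connectome constant, shuffles the loneliness labels B times,
#' refits the full PLS mode per shuffle, and records the (positively oriented)
#' Pearson correlation between scores and shuffled labels. The p-value uses
#' the add-one formula `(1 + #\{null >= observed\}) / (1 + B)` (one-sided).
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param B Number of permutations (default 1000).
#' @param seed Optional seed for the shuffles.
#' @return List of class `lb_permutation`: `observed`, `null_stats`,
#'   `p_value`, `B`, `seed`, and the fitted `mode`.
#' @export
permutation_test <- function(X, y, B = 1000, seed = NULL) {
  if (B < 1) abort("B must be >= 1")
  mode <- fit_pls_mode(X, y)
  pr <- pls_prepare(X, y)
  null_stats <- numeric(B)
  sy <- sum(pr$yc^2)
  with_seed(seed, {
    block <- 200L
    done <- 0L
    while (done < B) {
      b <- min(block, B - done)
      # refit per shuffle, vectorized: weights_perm = normalize(t(X) yc_perm),
      # stat = |cor(X w, yc_perm)| (positive orientation)
      Yp <- replicate(b, sample(pr$yc))
      Wp <- crossprod(pr$Xc, Yp)                      # E x b
      Wp <- sweep(Wp, 2, sqrt(colSums(Wp^2)), `/`)
      Sp <- pr$Xc %*% Wp                              # n x b
      num <- colSums(Sp * Yp)
      den <- sqrt(colSums(sweep(Sp, 2, colMeans(Sp))^2) * sy)
      null_stats[done + seq_len(b)] <- abs(num / den)
      done <- done + b
    }
  })
  p <- (1 + sum(null_stats >= mode$mode_corr)) / (1 + B)
  structure(list(observed = mode$mode_corr, null_stats = null_stats,
                 p_value = p, B = B, seed = seed, mode = mode),
            class = "lb_permutation")
}

#' Average edge weights into network-by-network blocks
#'
#' Entry (a, b) is the mean weight over all edges with one region in network a
#' and the other in network b (a = b: within-network edges). Symmetric.
#'
#' @param mode An `lb_pls_mode`, or a plain edge-weight vector.
#' @param atlas Atlas tibble matching the edge count.
#' @return 7 x 7 (or #networks squared) symmetric matrix with network names.
#' @export
network_block_summary <- function(mode, atlas = load_atlas()) {
  w <- if (inherits(mode, "lb_pls_mode")) mode$x_weights else as.numeric(mode)
  R <- nrow(atlas)
  if (length(w) != R * (R - 1) / 2) {
    abort("edge count does not match the atlas")
  }
  ei <- edge_index(R)
  nets <- atlas_networks(atlas)
  K <- length(canonical_networks())
  a <- pmin(atlas$network_index[ei$i], atlas$network_index[ei$j])
  b <- pmax(atlas$network_index[ei$i], atlas$network_index[ei$j])
  sums <- matrix(0, K, K); cnts <- matrix(0, K, K)
  for (e in seq_along(w)) {
    sums[a[e], b[e]] <- sums[a[e], b[e]] + w[e]
    cnts[a[e], b[e]] <- cnts[a[e], b[e]] + 1
  }
  blk <- sums / cnts
  blk[lower.tri(blk)] <- t(blk)[lower.tri(blk)]
  keep <- sort(unique(atlas$network_index))
  blk <- blk[keep, keep, drop = FALSE]
  dimnames(blk) <- list(canonical_networks()[keep], canonical_networks()[keep])
  blk
}

#' @export
print.lb_pls_mode <- function(x, ...) {
  cat("<lb_pls_mode> k =", x$k, "| n =", x$n,
      "| mode_corr =", sprintf("%.4f", x$mode_corr), "\n")
  invisible(x)
}

#' @export
print.lb_permutation <- function(x, ...) {
  cat("<lb_permutation> observed rho =", sprintf("%.4f", x$observed),
      "| B =", x$B, "| p =", sprintf("%.4g", x$p_value), "\n")
  invisible(x)
}
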