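#' Bonferroni family-wise error adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Number of tests in the family (>= 1).
#' @return `pmin(1, m * p)`.
#' @export
adjust_bonferroni <- function(p, m) {
  if (m < 1) abort("m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Associate tract microstructure with loneliness
#'
#' Per tract: Pearson correlation (equals the point-biserial correlation for
#' the binary label) and Spearman rank correlation with two-sided p-values,
#' Bonferroni correction at the family size (m = number of tracts, applied
#' separately within the linear and the rank family), percentile bootstrap
#' 5-95% intervals for the Pearson coefficient, and ranking by |Pearson rho|
#' (ties broken by catalog order).
#'
#' @param fa Numeric matrix (participants x tracts) of mean-FA values,
#'   deconfounded upstream.
#' @param y Binary loneliness labels.
#' @param catalog Tract catalog; column order of `fa` must match.
#' @param bootstrap Number of bootstrap resamples for the CIs (default 100);
#'   set to 0 to skip.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble of class `lb_tract_assoc` with columns `tract`,
#'   `pearson_rho`, `spearman_rho`, `ci_low`, `ci_high`, `p_raw`,
#'   `p_bonferroni` (Pearson family), `p_spearman_raw`,
#'   `p_spearman_bonferroni`, `rank`.
#' @export
tract_associations <- function(fa, y, catalog = load_tract_catalog(),
                               bootstrap = 100, seed = NULL) {
  fa <- as.matrix(fa)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("y must contain both classes")
  if (ncol(fa) != nrow(catalog)) {
    abort("fa column count does not match the tract catalog")
  }
  sds <- apply(fa, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant FA column(s): ",
                 paste(catalog$tract[sds == 0], collapse = ", ")))
  }
  m <- ncol(fa)
  pe <- lapply(seq_len(m), function(jj) cor.test(fa[, jj], y, method = "pearson"))
  sp <- lapply(seq_len(m), function(jj) {
    suppressWarnings(cor.test(fa[, jj], y, method = "spearman", exact = FALSE))
  })
  pearson_rho <- vapply(pe, function(z) unname(z$estimate), numeric(1))
  p_raw <- vapply(pe, function(z) z$p.value, numeric(1))
  spearman_rho <- vapply(sp, function(z) unname(z$estimate), numeric(1))
  p_sp <- vapply(sp, function(z) z$p.value, numeric(1))

  ci <- if (bootstrap >= 2) {
    bootstrap_cis(fa, y, B = bootstrap, seed = seed)
  } else {
    tibble(ci_low = rep(NA_real_, m), ci_high = rep(NA_real_, m))
  }

  # rank by |pearson| descending; ties keep catalog order
  rk <- integer(m)
  rk[order(-abs(pearson_rho), seq_len(m))] <- seq_len(m)

  out <- tibble(
    tract = catalog$tract,
    pearson_rho = pearson_rho,
    spearman_rho = spearman_rho,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    p_raw = p_raw,
    p_bonferroni = adjust_bonferroni(p_raw, m),
    p_spearman_raw = p_sp,
    p_spearman_bonferroni = adjust_bonferroni(p_sp, m),
    rank = rk
  )
  class(out) <- c("lb_tract_assoc", class(out))
  out
}

#' Percentile bootstrap intervals for tract correlations
#'
#' Resamples participants with replacement B times, recomputes the Pearson
#' correlation per tract, and returns the 5th and 95th percentiles of the B
#' estimates. A resample that loses one outcome class is redrawn (up to a
#' retry cap) and logged.
#'
#' @param fa Numeric matrix (participants x tracts).
#' @param y Binary labels.
#' @param B Number of resamples (default 100, >= 2).
#' @param seed Optional seed.
#' @param retry_cap Maximum redraws for single-class resamples.
#' @return Tibble with `ci_low`, `ci_high` (one row per tract).
#' @export
bootstrap_cis <- function(fa, y, B = 100, seed = NULL, retry_cap = 100) {
  if (B < 2) abort("B must be >= 2")
  fa <- as.matrix(fa)
  y <- as.numeric(y)
  n <- nrow(fa)
  with_seed(seed, {
    est <- matrix(NA_real_, B, ncol(fa))
    redraws <- 0
    for (b in seq_len(B)) {
      for (try in seq_len(retry_cap + 1)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) >= 2 &&
            all(matrixStats_colSds(fa[idx, , drop = FALSE]) > 0)) break
        redraws <- redraws + 1
        if (try > retry_cap) abort("bootstrap retry cap exceeded (degenerate resamples)")
      }
      est[b, ] <- suppressWarnings(drop(cor(y[idx], fa[idx, , drop = FALSE])))
    }
    if (redraws > 0) {
      message("bootstrap_cis: redrew ", redraws, " degenerate resample(s)")
    }
    qs <- apply(est, 2, quantile, probs = c(0.05, 0.95), names = FALSE,
                type = 7, na.rm = TRUE)
    tibble(ci_low = qs[1, ], ci_high = qs[2, ])
  })
}

# column sds without extra dependencies
matrixStats_colSds <- function(m) {
  nr <- nrow(m)
  cm <- colMeans(m)
  sqrt(pmax(0, (colSums(m^2) - nr * cm^2) / (nr - 1)))
}

#' @export
print.lb_tract_assoc <- function(x, ...) {
  cat("<lb_tract_assoc>", nrow(x), "tracts; strongest associations first:\n")
  y <- dplyr::arrange(as_tibble(x), .data$rank)
  print(y, ...)
  invisible(x)
}
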