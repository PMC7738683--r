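#' Fit the Bayesian hierarchical volume model
#'
#' Hierarchical logistic regression of the binary loneliness label on 100
#' region gray-matter volumes (deconfounded and z-scored upstream), with
#' region slopes partially pooled within the seven canonical networks and
#' sex-specific intercepts and age slopes as nuisance terms:
#'
#' \deqn{y \sim Bernoulli(p), \quad logit(p) = \sum_r x_r \beta_r +
#'   \alpha_{men} + \alpha_{women} + \alpha_{men\_age} age +
#'   \alpha_{women\_age} age}
#'
#' Two model forms are available. `model = "network"` (the variance-component
#' form): all regions of network k share one scale, \eqn{\beta_r \sim
#' N(0, \sigma_{k(r)}^2)}, so the seven \eqn{\sigma_k} directly quantify each
#' network's overall relevance. `model = "region"`: every region has its own
#' scale \eqn{\sigma_r} (diagonal network covariance, the displayed per-region
#' form). Scales get half-normal(1) priors (sampled on the log scale); the
#' \eqn{\alpha} terms get N(0, 1). With `stratify_sex = TRUE` the beta block
#' (and its scales) is duplicated for men and women, estimated jointly.
#'
#' Posterior sampling uses the package's built-in No-U-Turn sampler (dynamic
#' Hamiltonian Monte Carlo with dual-averaging step-size adaptation and a
#' diagonal metric learned during warmup), on the non-centered
#' parameterization. Chains run sequentially under R's RNG, so a single
#' `seed` makes the whole fit reproducible.
#'
#' @param volumes Numeric matrix (participants x regions); each column must be
#'   mean 0, sd 1 (tolerance 1e-6) — use [deconfound()] first.
#' @param cohort Data frame with columns `loneliness` (0/1), `sex` (1 = man),
#'   and `age_z` (z-scored age).
#' @param atlas Atlas tibble; `ncol(volumes)` must equal its region count.
#' @param model `"network"` (shared scale per network) or `"region"`
#'   (per-region scales).
#' @param stratify_sex Duplicate region parameters for men and women.
#' @param chains,tune,draws Sampler settings. Defaults: 4 chains, 1000 warmup
#'   ("tune") iterations, 1000 retained draws per chain.
#' @param long_warmup Use the heavier preset of 4000 tuning steps and 1000
#'   draws.
#' @param target_accept,max_treedepth NUTS tuning (defaults 0.8 and 10).
#' @param seed Seed for the chains.
#' @return Object of class `lb_volume_fit`: `draws` (chains x draws x
#'   parameters array with parameter names), `atlas`, `model`, `stratify_sex`,
#'   `sampler` diagnostics tibble, and the settings.
#' @export
fit_volume_model <- function(volumes, cohort, atlas = load_atlas(),
                             model = c("network", "region"),
                             stratify_sex = FALSE,
                             chains = 4, tune = 1000, draws = 1000,
                             long_warmup = FALSE,
                             target_accept = 0.8, max_treedepth = 10,
                             seed = NULL) {
  model <- match.arg(model)
  X <- as.matrix(volumes)
  p <- ncol(X)
  if (p != nrow(atlas)) {
    abort(paste0("volumes has ", p, " columns but the atlas has ",
                 nrow(atlas), " regions"))
  }
  need <- c("loneliness", "sex", "age_z")
  if (!all(need %in% names(cohort))) {
    abort(paste0("cohort must have columns ", paste(need, collapse = ", ")))
  }
  y <- as.numeric(cohort$loneliness)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("loneliness must be binary with both classes present")
  }
  cm <- colMeans(X)
  csd <- apply(X, 2, sd)
  if (max(abs(cm)) > 1e-6 || max(abs(csd - 1)) > 1e-6) {
    abort("volume columns must be z-scored (mean 0, sd 1); run deconfound() first")
  }
  if (chains < 2) abort("need at least 2 chains for convergence diagnostics")
  if (long_warmup) { tune <- 4000; draws <- 1000 }

  sex <- as.integer(cohort$sex)
  age_z <- as.numeric(cohort$age_z)
  scale_idx <- if (model == "network") {
    match(atlas$network_index, sort(unique(atlas$network_index))) - 1L
  } else {
    seq_len(p) - 1L
  }
  group <- if (stratify_sex) 1L - sex else rep(0L, length(y))  # 0 = men group
  G <- if (stratify_sex) 2L else 1L
  K <- if (model == "network") length(unique(scale_idx)) else p

  groups <- if (stratify_sex) c("men", "women") else "pooled"
  bnames <- unlist(lapply(groups, function(g) {
    if (G == 1) paste0("beta[", atlas$name, "]")
    else paste0("beta[", atlas$name, ",", g, "]")
  }))
  snames <- unlist(lapply(groups, function(g) {
    base <- if (model == "network") {
      paste0("sigma[", canonical_networks()[sort(unique(atlas$network_index))], "]")
    } else {
      paste0("sigma_region[", atlas$name, "]")
    }
    if (G == 1) base else sub("\\]$", paste0(",", g, "]"), base)
  }))
  pnames <- c(bnames, snames,
              "alpha_men", "alpha_women", "alpha_men_age", "alpha_women_age")

  res <- with_seed(seed, {
    lapply(seq_len(chains), function(ch) {
      .nuts_chain(X, y, sex, age_z, scale_idx, group,
                  as.integer(tune), as.integer(draws),
                  target_accept, as.integer(max_treedepth), 0.5)
    })
  })

  arr <- array(NA_real_, dim = c(chains, draws, length(pnames)),
               dimnames = list(chain = NULL, draw = NULL, parameter = pnames))
  for (ch in seq_len(chains)) arr[ch, , ] <- res[[ch]]$draws
  diag_tbl <- tibble(
    chain = seq_len(chains),
    divergences = vapply(res, `[[`, numeric(1), "divergences"),
    max_depth_hits = vapply(res, `[[`, numeric(1), "max_depth_hits"),
    mean_accept = vapply(res, `[[`, numeric(1), "mean_accept"),
    step_size = vapply(res, `[[`, numeric(1), "step_size")
  )
  structure(list(draws = arr, atlas = atlas, model = model,
                 stratify_sex = stratify_sex, groups = groups,
                 sampler = diag_tbl, n = nrow(X), p = p,
                 settings = list(chains = chains, tune = tune, draws = draws,
                                 target_accept = target_accept,
                                 max_treedepth = max_treedepth, seed = seed)),
            class = "lb_volume_fit")
}

#' Highest-posterior-density interval
#'
#' Narrowest interval containing a given posterior mass, computed by scanning
#' windows of the sorted draws (for a unimodal posterior this is the HDI;
#' "5-95% HPD" corresponds to the default `prob = 0.90`).
#'
#' @param samples Numeric vector of posterior draws.
#' @param prob Mass to contain (default 0.90).
#' @return Named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.90) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) abort("no samples")
  if (!(prob > 0 && prob <= 1)) abort("prob must be in (0, 1]")
  xs <- sort(samples)
  n <- length(xs)
  m <- min(n, ceiling(prob * n))
  if (m == n) return(c(lower = xs[1], upper = xs[n]))
  starts <- seq_len(n - m + 1)
  widths <- xs[starts + m - 1] - xs[starts]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Central (equal-tailed) posterior interval
#'
#' The 5th-95th percentile alternative to [hpd_interval()]; for symmetric
#' unimodal posteriors the two coincide.
#'
#' @param samples Numeric vector of draws.
#' @param prob Central mass (default 0.90).
#' @return Named vector `c(lower, upper)`.
#' @export
central_interval <- function(samples, prob = 0.90) {
  a <- (1 - prob) / 2
  q <- quantile(samples, c(a, 1 - a), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Split-Rhat convergence diagnostic
#'
#' Classic split-\eqn{\hat R}: each chain is split in half and the
#' between/within variance ratio is computed over the 2m half-chains. Values
#' near 1 indicate convergence; the package's convergence criterion is
#' \eqn{\hat R \le 1.02}. Constant chains return 1 with a warning.
#'
#' @param draws A chains x samples matrix, or a list of equal-length chains.
#' @return A single \eqn{\hat R} value.
#' @export
compute_rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(rbind, draws)
  draws <- as.matrix(draws)
  if (nrow(draws) < 2) abort("need at least 2 chains")
  if (ncol(draws) < 4) abort("need at least 4 samples per chain")
  half <- floor(ncol(draws) / 2)
  split <- rbind(draws[, seq_len(half), drop = FALSE],
                 draws[, half + seq_len(half), drop = FALSE])
  m <- nrow(split); nn <- ncol(split)
  means <- rowMeans(split)
  vars <- apply(split, 1, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) {
    warn("constant chains; Rhat defined as 1")
    return(1)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Tidy posterior summary of a volume-model fit
#'
#' One row per parameter: posterior mean, HPD bounds, split-Rhat, and for
#' region coefficients a flag (`"positive"` if the whole interval is above
#' zero, `"negative"` if below, else `"none"`).
#'
#' @param x An `lb_volume_fit`.
#' @param prob Interval mass (default 0.90, i.e. 5-95%).
#' @param interval `"hpd"` (default) or `"central"`.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `kind`, `group`, `region`,
#'   `network`, `mean`, `hpd_low`, `hpd_high`, `rhat`, `flag`.
#' @export
tidy.lb_volume_fit <- function(x, prob = 0.90, interval = c("hpd", "central"),
                               ...) {
  interval <- match.arg(interval)
  ifun <- if (interval == "hpd") hpd_interval else central_interval
  pn <- dimnames(x$draws)$parameter
  stats <- lapply(pn, function(par) {
    d <- x$draws[, , par, drop = TRUE]
    ci <- ifun(as.vector(d), prob)
    tibble(parameter = par, mean = mean(d),
           hpd_low = ci[["lower"]], hpd_high = ci[["upper"]],
           rhat = suppressWarnings(compute_rhat(d)))
  })
  out <- dplyr::bind_rows(stats)
  out$kind <- dplyr::case_when(
    grepl("^beta\\[", out$parameter) ~ "beta",
    grepl("^sigma", out$parameter) ~ "sigma",
    TRUE ~ "alpha"
  )
  lab <- sub("^[a-z_]+\\[", "", sub("\\]$", "", out$parameter))
  parts <- strsplit(lab, ",", fixed = TRUE)
  first <- vapply(parts, `[`, character(1), 1)
  second <- vapply(parts, function(z) if (length(z) > 1) z[2] else NA_character_,
                   character(1))
  out$group <- ifelse(out$kind == "alpha", NA_character_,
                      ifelse(is.na(second), "pooled", second))
  out$region <- ifelse(out$kind == "beta" |
                         grepl("^sigma_region", out$parameter), first, NA)
  out$network <- NA_character_
  is_reg <- !is.na(out$region)
  out$network[is_reg] <- x$atlas$network[match(out$region[is_reg], x$atlas$name)]
  out$network[out$kind == "sigma" & !is_reg] <- first[out$kind == "sigma" & !is_reg]
  out$flag <- dplyr::case_when(
    out$kind != "beta" ~ NA_character_,
    out$hpd_low > 0 ~ "positive",
    out$hpd_high < 0 ~ "negative",
    TRUE ~ "none"
  )
  dplyr::select(out, "parameter", "kind", "group", "region", "network",
                "mean", "hpd_low", "hpd_high", "rhat", "flag")
}

#' One-line fit summary
#'
#' @param x An `lb_volume_fit`.
#' @param ... Unused.
#' @return Tibble with sample size, model form, sampler settings, max Rhat and
#'   total divergences.
#' @export
glance.lb_volume_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(n = x$n, p = x$p, model = x$model, stratify_sex = x$stratify_sex,
         chains = x$settings$chains, tune = x$settings$tune,
         draws = x$settings$draws,
         max_rhat = max(td$rhat), divergences = sum(x$sampler$divergences))
}

#' Rank networks by posterior variance-component magnitude
#'
#' Networks ordered from most to least explanatory by the posterior mean of
#' their scale parameter sigma (ties broken by canonical network order).
#' Requires a network-level fit.
#'
#' @param fit An `lb_volume_fit` with `model = "network"`.
#' @param group For stratified fits, which group's sigmas to rank.
#' @param prob Interval mass.
#' @return Tibble: `network`, `sigma_mean`, `hpd_low`, `hpd_high`, `rank`.
#' @export
network_ranking <- function(fit, group = NULL, prob = 0.90) {
  if (fit$model != "network") abort("network_ranking needs a network-level fit")
  td <- tidy(fit, prob = prob)
  td <- td[td$kind == "sigma", ]
  if (fit$stratify_sex) {
    group <- group %||% "men"
    td <- td[td$group == group, ]
  }
  ord <- order(-td$mean, match(td$network, canonical_networks()))
  td <- td[ord, ]
  tibble(network = td$network, sigma_mean = td$mean,
         hpd_low = td$hpd_low, hpd_high = td$hpd_high,
         rank = seq_len(nrow(td)))
}

#' Flag regions whose posterior interval excludes zero
#'
#' A region is flagged positive when its HPD lower bound is above zero and
#' negative when its upper bound is below zero (the thresholding used to
#' display region effects).
#'
#' @param x An `lb_volume_fit` or a tidy summary tibble with beta rows.
#' @param prob Interval mass (when `x` is a fit).
#' @return Tibble of flagged regions: `region`, `network`, `group`, `mean`,
#'   `hpd_low`, `hpd_high`, `flag`.
#' @export
threshold_regions <- function(x, prob = 0.90) {
  td <- if (inherits(x, "lb_volume_fit")) tidy(x, prob = prob) else x
  td <- td[td$kind == "beta", ]
  td$flag <- ifelse(td$hpd_low > 0, "positive",
                    ifelse(td$hpd_high < 0, "negative", "none"))
  td <- td[td$flag != "none", ]
  dplyr::select(td, "region", "network", "group", "mean",
                "hpd_low", "hpd_high", "flag")
}

#' @export
print.lb_volume_fit <- function(x, ...) {
  g <- glance(x)
  cat("<lb_volume_fit>", x$model, "model",
      if (x$stratify_sex) "(sex-stratified)" else "(pooled)",
      "| n =", g$n, "| chains =", g$chains,
      "| max Rhat =", sprintf("%.3f", g$max_rhat),
      "| divergences =", g$divergences, "\n")
  if (x$model == "network" && !x$stratify_sex) {
    print(network_ranking(x))
  }
  invisible(x)
}
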