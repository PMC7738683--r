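#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the population cohort the package is designed around:
#' n = 38,701 participants, 13.1% loneliness prevalence, 47.5% men, ages
#' 40-69, and planted effects sized like the reported population estimates —
#' network-level volume-effect scales largest for the default network
#' (sigma = 0.07), a default-network-dominant functional-connectivity mode,
#' and small fornix-tract point-biserial correlations (0.06 / 0.05 / 0.05).
#'
#' @param n Cohort size.
#' @param sigma_per_network Named non-negative scales of the region volume
#'   effects, one per canonical network. Regions in network k get a true
#'   logistic slope drawn from N(0, sigma_k^2).
#' @param within_network_volume_corr Exchangeable correlation of volumes
#'   within a network, in `[0, 1)`; induced by a shared network factor.
#' @param target_prevalence Target loneliness proportion; the generator
#'   calibrates the logistic intercept by bisection to hit it in expectation.
#' @param alpha_men,alpha_women Sex-specific intercept shifts (log-odds).
#' @param alpha_men_age,alpha_women_age Sex-specific slopes on z-scored age.
#' @param fc_mode_strength Strength of the planted connectivity mode: edge
#'   matrix is unit noise plus `strength * centered(label) * mode`, with the
#'   mode a unit-norm default-network-dominant edge pattern.
#' @param tract_rho Named length-48 vector of target point-biserial
#'   correlations between tract FA and the loneliness label. Each FA column is
#'   constructed as `rho * standardized(label) + sqrt(1 - rho^2) * noise`, so
#'   the population correlation is exactly `rho`.
#' @param confound_loadings Optional named list: confound name ->
#'   per-block loadings, either a single number or a named vector with any of
#'   `volumes`, `fc`, `fa`. The z-scored confound times the loading is added
#'   to every column of the block.
#' @param prop_men Proportion of men in the cohort.
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `lb_generator_config`.
#' @export
generator_config <- function(n = 38701,
                             sigma_per_network = c(Visual = 0.04, SomMot = 0.04,
                                                   DorsalAttn = 0.05, Salience = 0.02,
                                                   Limbic = 0.06, Control = 0.03,
                                                   Default = 0.07),
                             within_network_volume_corr = 0.3,
                             target_prevalence = 0.131,
                             alpha_men = 0, alpha_women = 0,
                             alpha_men_age = 0, alpha_women_age = 0,
                             fc_mode_strength = 1,
                             tract_rho = NULL,
                             confound_loadings = NULL,
                             prop_men = 0.475,
                             seed = 1L) {
  if (is.null(tract_rho)) {
    catalog <- load_tract_catalog()
    tract_rho <- setNames(rep(0, nrow(catalog)), catalog$tract)
    tract_rho["Fornix (column and body)"] <- 0.06
    tract_rho["Fornix (cres) / Stria terminalis L"] <- 0.05
    tract_rho["Fornix (cres) / Stria terminalis R"] <- 0.05
  }
  if (length(sigma_per_network) != 7) abort("sigma_per_network must have 7 entries")
  if (is.null(names(sigma_per_network))) {
    names(sigma_per_network) <- canonical_networks()
  }
  if (!setequal(names(sigma_per_network), canonical_networks())) {
    abort("sigma_per_network names must be the 7 canonical networks")
  }
  sigma_per_network <- sigma_per_network[canonical_networks()]
  if (any(sigma_per_network < 0)) abort("sigma_per_network must be non-negative")
  if (length(tract_rho) != 48) abort("tract_rho must have 48 entries")
  if (any(abs(tract_rho) >= 1)) abort("tract_rho must lie in (-1, 1)")
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    abort("target_prevalence must be in (0, 1)")
  }
  if (within_network_volume_corr < 0 || within_network_volume_corr >= 1) {
    abort("within_network_volume_corr must be in [0, 1)")
  }
  structure(list(
    n = as.integer(n),
    sigma_per_network = sigma_per_network,
    within_network_volume_corr = within_network_volume_corr,
    target_prevalence = target_prevalence,
    alpha_men = alpha_men, alpha_women = alpha_women,
    alpha_men_age = alpha_men_age, alpha_women_age = alpha_women_age,
    fc_mode_strength = fc_mode_strength,
    tract_rho = tract_rho,
    confound_loadings = confound_loadings,
    prop_men = prop_men,
    seed = seed
  ), class = "lb_generator_config")
}

#' Draw per-region true effects from network-level scales
#'
#' Region r gets a slope drawn from a zero-mean Gaussian whose scale is the
#' sigma of r's network (the generative counterpart of the hierarchical
#' model's network variance components).
#'
#' @param sigmas Named length-7 non-negative vector (canonical networks).
#' @param atlas Atlas tibble from [load_atlas()].
#' @param seed Optional seed.
#' @return Numeric vector, one effect per region (atlas order).
#' @export
sample_region_betas <- function(sigmas, atlas = load_atlas(), seed = NULL) {
  if (any(sigmas < 0)) abort("sigmas must be non-negative")
  if (length(sigmas) != 7) abort("sigmas must have 7 entries (canonical networks)")
  if (!is.null(names(sigmas))) sigmas <- sigmas[canonical_networks()]
  with_seed(seed, rnorm(nrow(atlas), 0, sigmas[atlas$network_index]))
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Finds `c` such that `mean(plogis(c + linear_predictor))` equals `target`,
#' by bisection to 1e-6.
#'
#' @param linear_predictor Numeric vector of logit-scale contributions.
#' @param target Target proportion in (0, 1).
#' @return The intercept (a single number).
#' @export
calibrate_intercept <- function(linear_predictor, target) {
  if (!(target > 0 && target < 1)) abort("target must be in (0, 1)")
  if (any(!is.finite(linear_predictor))) {
    abort("linear_predictor contains non-finite values")
  }
  f <- function(c) mean(plogis(c + linear_predictor)) - target
  lo <- qlogis(target) - max(abs(linear_predictor)) - 1
  hi <- qlogis(target) + max(abs(linear_predictor)) + 1
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  stopifnot(abs(f(mid)) < 1e-6)
  mid
}

#' Default-network-dominant planted connectivity mode
#'
#' Unit-norm edge-weight pattern used as the generator's ground-truth
#' connectivity mode: positive weights inside the default network (and its
#' couplings to limbic, dorsal-attention and somatomotor networks), positive
#' within the visual network, and negative between the visual network and
#' everything else — the qualitative pattern of the reported population mode.
#'
#' @param atlas Atlas tibble.
#' @return Unit-norm numeric vector of length `R(R-1)/2`.
#' @export
planted_default_mode <- function(atlas = load_atlas()) {
  ei <- edge_index(nrow(atlas))
  ni <- atlas$network_index[ei$i]
  nj <- atlas$network_index[ei$j]
  nets <- canonical_networks()
  w <- numeric(nrow(ei))
  dn <- which(nets == "Default"); vis <- which(nets == "Visual")
  up <- match(c("Limbic", "DorsalAttn", "SomMot"), nets)
  w[ni == dn & nj == dn] <- 1
  w[ni == vis & nj == vis] <- 0.6
  w[(ni == vis) != (nj == vis)] <- -0.6
  between_dn <- ((ni == dn & nj %in% up) | (nj == dn & ni %in% up))
  w[between_dn] <- 0.3
  w / sqrt(sum(w^2))
}

#' Generate a synthetic population cohort with known ground truth
#'
#' Simulates the three imaging-derived feature blocks plus phenotype under the
#' generative model the analysis stages assume: region volumes with
#' exchangeable within-network correlation and a hierarchical logistic
#' loneliness model; connectome edges with a planted default-network-dominant
#' mode; tract FA with exact target point-biserial correlations; optional
#' confound contamination.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed`). Per-block sub-seeds are
#'   derived from it, so e.g. the volume block is identical whether or not the
#'   connectivity block is generated.
#' @param blocks Which feature blocks to generate (subset of
#'   `c("volumes", "fc", "fa")`). Phenotypes always generated.
#' @param atlas,catalog Atlas and tract catalog.
#' @return A list of class `lb_cohort`: `cohort` (tibble with participant_id,
#'   loneliness, sex, age and confound columns), `volumes` (n x 100),
#'   `fc_edges` (n x 4950), `fa` (n x 48) and `truth` (generating parameters).
#' @export
generate_cohort <- function(config = generator_config(),
                            seed = config$seed,
                            blocks = c("volumes", "fc", "fa"),
                            atlas = load_atlas(),
                            catalog = load_tract_catalog()) {
  stopifnot(inherits(config, "lb_generator_config"))
  blocks <- match.arg(blocks, several.ok = TRUE)
  n <- config$n
  p <- nrow(atlas)
  nets <- atlas$network_index

  # --- phenotype frame and confounds ---------------------------------------
  ph <- with_seed(derive_seed(seed, "phenotype"), {
    sex <- rbinom(n, 1, config$prop_men)            # 1 = man
    age <- runif(n, 40, 69)
    tibble(
      participant_id = sprintf("P%06d", seq_len(n)),
      sex = sex,
      age = age,
      age_z = as.numeric(scale(age)),
      bmi = rnorm(n, 27, 4),
      head_size = rnorm(n),
      motion_task = rnorm(n),
      motion_rest = rnorm(n),
      head_pos_x = rnorm(n), head_pos_y = rnorm(n), head_pos_z = rnorm(n),
      table_pos = rnorm(n),
      site = sample(c("site_A", "site_B", "site_C"), n, replace = TRUE)
    )
  })

  # --- volumes: shared network factor gives exchangeable correlation -------
  rho <- config$within_network_volume_corr
  volumes <- with_seed(derive_seed(seed, "volumes"), {
    f <- matrix(rnorm(n * 7), n, 7)
    v <- sqrt(rho) * f[, nets, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    colnames(v) <- atlas$name
    v
  })

  # --- outcome from the hierarchical logistic model ------------------------
  beta <- sample_region_betas(config$sigma_per_network, atlas,
                              seed = derive_seed(seed, "betas"))
  eta <- drop(volumes %*% beta) +
    ifelse(ph$sex == 1,
           config$alpha_men + config$alpha_men_age * ph$age_z,
           config$alpha_women + config$alpha_women_age * ph$age_z)
  intercept <- calibrate_intercept(eta, config$target_prevalence)
  y <- with_seed(derive_seed(seed, "outcome"),
                 rbinom(n, 1, plogis(intercept + eta)))
  ph <- dplyr::mutate(ph, loneliness = y, .after = "participant_id")
  if (length(unique(y)) < 2) abort("degenerate cohort: single outcome class")

  label_c <- (2 * y - 1) - mean(2 * y - 1)
  label_z <- label_c / sd(label_c)

  # --- functional connectome edges -----------------------------------------
  mode <- planted_default_mode(atlas)
  fc_edges <- NULL
  if ("fc" %in% blocks) {
    fc_edges <- with_seed(derive_seed(seed, "fc"), {
      m <- matrix(rnorm(n * length(mode)), n, length(mode))
      m + tcrossprod(label_c, config$fc_mode_strength * mode)
    })
  }

  # --- tract FA: exact population point-biserial correlation ---------------
  fa <- NULL
  if ("fa" %in% blocks) {
    tr <- config$tract_rho
    fa <- with_seed(derive_seed(seed, "fa"), {
      noise <- matrix(rnorm(n * 48), n, 48)
      m <- outer(label_z, tr) + sweep(noise, 2, sqrt(1 - tr^2), `*`)
      colnames(m) <- catalog$tract
      m
    })
  }

  # --- confound contamination ----------------------------------------------
  if (!is.null(config$confound_loadings)) {
    for (cf in names(config$confound_loadings)) {
      ld <- config$confound_loadings[[cf]]
      if (is.null(names(ld))) ld <- c(volumes = ld[1], fc = ld[1], fa = ld[1])
      cz <- as.numeric(scale(ph[[cf]]))
      if (!is.na(ld["volumes"]) && ld["volumes"] != 0) {
        volumes <- volumes + ld[["volumes"]] * cz
      }
      if ("fc" %in% blocks && !is.na(ld["fc"]) && ld["fc"] != 0) {
        fc_edges <- fc_edges + ld[["fc"]] * cz
      }
      if ("fa" %in% blocks && !is.na(ld["fa"]) && ld["fa"] != 0) {
        fa <- fa + ld[["fa"]] * cz
      }
    }
  }

  structure(list(
    cohort = ph,
    volumes = if ("volumes" %in% blocks) volumes else NULL,
    fc_edges = fc_edges,
    fa = fa,
    truth = list(beta_region = setNames(beta, atlas$name),
                 sigma_per_network = config$sigma_per_network,
                 intercept = intercept,
                 planted_mode = mode,
                 tract_rho = config$tract_rho,
                 seed = seed,
                 config = config)
  ), class = "lb_cohort")
}

#' @export
print.lb_cohort <- function(x, ...) {
  cat("<lb_cohort> n =", nrow(x$cohort),
      "| prevalence =", sprintf("%.3f", mean(x$cohort$loneliness)),
      "| blocks:",
      paste(c("volumes", "fc_edges", "fa")[!vapply(
        x[c("volumes", "fc_edges", "fa")], is.null, logical(1))],
        collapse = ", "),
      "\n")
  invisible(x)
}
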