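# helper: z-scored design + outcome from a logistic model on a tiny atlas
toy_model_data <- function(n, atlas, beta, seed = 1, alpha = qlogis(0.2)) {
  set.seed(seed)
  X <- standardize(matrix(rnorm(n * nrow(atlas)), n, nrow(atlas)))
  colnames(X) <- atlas$name
  ch <- fake_cohort_frame(n, seed = seed + 1)
  eta <- alpha + drop(X %*% beta)
  ch$loneliness <- rbinom(n, 1, plogis(eta))
  list(X = X, cohort = ch)
}

test_that("hpd interval matches a grid-search oracle and handles edge cases", {
  expect_equal(hpd_interval(rep(3.5, 200)), c(lower = 3.5, upper = 3.5))
  x <- rnorm(500)
  expect_equal(hpd_interval(x, prob = 1), c(lower = min(x), upper = max(x)))
  expect_error(hpd_interval(numeric(0)), "no samples")

  set.seed(42)
  z <- rnorm(1e5)
  got <- hpd_interval(z, 0.90)
  # central 90% of a standard normal
  expect_lt(abs(got[["lower"]] - (-1.6449)), 0.03)
  expect_lt(abs(got[["upper"]] - 1.6449), 0.03)
  # independent grid-search oracle over interval start quantiles
  grid <- seq(0, 0.10, length.out = 4001)
  lo <- quantile(z, grid, names = FALSE)
  hi <- quantile(z, grid + 0.90, names = FALSE)
  k <- which.min(hi - lo)
  expect_lt(abs(got[["lower"]] - lo[k]), 0.01)
  expect_lt(abs(got[["upper"]] - hi[k]), 0.01)

  skip_if_not_installed("coda")
  ref <- coda::HPDinterval(coda::as.mcmc(z), prob = 0.90)
  expect_lt(abs(got[["lower"]] - ref[1, "lower"]), 0.01)
  expect_lt(abs(got[["upper"]] - ref[1, "upper"]), 0.01)
})

test_that("split-Rhat matches an independently coded formula", {
  set.seed(1)
  conv <- rbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(compute_rhat(conv) - 1), 0.01)
  bad <- rbind(rnorm(400), rnorm(400) + 5)
  expect_gt(compute_rhat(bad), 2)

  # formula oracle on a tiny 2 x 8 array, written out longhand
  d <- rbind(c(1.2, 0.8, 1.5, 0.3, 2.0, 1.1, 0.6, 1.4),
             c(0.9, 1.6, 0.2, 1.3, 1.8, 0.4, 1.0, 0.7))
  halves <- list(d[1, 1:4], d[1, 5:8], d[2, 1:4], d[2, 5:8])
  nn <- 4; m <- 4
  mu <- vapply(halves, mean, numeric(1))
  s2 <- vapply(halves, var, numeric(1))
  W <- mean(s2)
  B <- nn / (m - 1) * sum((mu - mean(mu))^2)
  oracle <- sqrt(((nn - 1) / nn * W + B / nn) / W)
  expect_equal(compute_rhat(d), oracle, tolerance = 1e-12)

  expect_error(compute_rhat(matrix(rnorm(100), 1)), "2 chains")
  expect_warning(r1 <- compute_rhat(matrix(2, 2, 10)), "constant")
  expect_equal(r1, 1)
})

test_that("model bookkeeping: parameter counts, names and input guards", {
  at <- tiny_atlas(c("Visual", "Default"), 3)  # 6 regions, 2 networks
  td <- toy_model_data(150, at, rep(0, 6))
  fit <- fit_volume_model(td$X, td$cohort, at, chains = 2, tune = 50,
                          draws = 50, seed = 1)
  pn <- dimnames(fit$draws)$parameter
  expect_length(pn, 6 + 2 + 4)  # betas + network sigmas + alphas
  expect_true(all(c("sigma[Visual]", "sigma[Default]", "alpha_men",
                    "alpha_women", "alpha_men_age", "alpha_women_age") %in% pn))

  fit2 <- fit_volume_model(td$X, td$cohort, at, model = "region",
                           stratify_sex = TRUE, chains = 2, tune = 50,
                           draws = 50, seed = 1)
  pn2 <- dimnames(fit2$draws)$parameter
  expect_length(grep("^beta\\[", pn2), 12)        # 6 regions x 2 groups
  expect_length(grep("^sigma_region\\[", pn2), 12)
  expect_length(pn2, 12 + 12 + 4)

  expect_error(fit_volume_model(td$X[, 1:5], td$cohort, at), "atlas")
  expect_error(fit_volume_model(td$X * 2, td$cohort, at), "z-scored")
  bad <- td$cohort; bad$loneliness <- 1
  expect_error(fit_volume_model(td$X, bad, at, chains = 2), "both classes")
})

test_that("fits are reproducible under a fixed seed", {
  at <- tiny_atlas(c("Visual", "Default"), 3)
  td <- toy_model_data(200, at, c(0.4, 0, 0, 0, 0, -0.2))
  f1 <- fit_volume_model(td$X, td$cohort, at, chains = 2, tune = 200,
                         draws = 200, seed = 7)
  f2 <- fit_volume_model(td$X, td$cohort, at, chains = 2, tune = 200,
                         draws = 200, seed = 7)
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior agrees with an independent Gibbs implementation (JAGS)", {
  skip_if_not_installed("rjags")
  at <- tiny_atlas(c("Visual", "Default"), 5)  # 10 regions, 2 networks
  set.seed(10)
  beta_true <- c(rnorm(5, 0, 0.1), rnorm(5, 0, 0.6))
  td <- toy_model_data(400, at, beta_true, seed = 10)
  fit <- fit_volume_model(td$X, td$cohort, at, chains = 2, tune = 1000,
                          draws = 2000, seed = 3)
  tdy <- tidy(fit)

  jm <- "
  model {
    for (i in 1:n) {
      logit(p[i]) <- inprod(X[i,], beta) +
        men[i] * (a_men + b_men * age[i]) +
        (1 - men[i]) * (a_wom + b_wom * age[i])
      y[i] ~ dbern(p[i])
    }
    for (r in 1:np) { beta[r] ~ dnorm(0, 1 / (sig[net[r]] * sig[net[r]])) }
    for (k in 1:K) { sig[k] ~ dnorm(0, 1) T(0,) }
    a_men ~ dnorm(0, 1); a_wom ~ dnorm(0, 1)
    b_men ~ dnorm(0, 1); b_wom ~ dnorm(0, 1)
  }"
  net <- match(at$network_index, sort(unique(at$network_index)))
  dat <- list(n = nrow(td$X), np = 10, K = 2, X = td$X,
              y = td$cohort$loneliness, men = td$cohort$sex,
              age = td$cohort$age_z, net = net)
  mod <- rjags::jags.model(textConnection(jm), data = dat, n.chains = 2,
                           n.adapt = 1000, quiet = TRUE,
                           inits = list(.RNG.name = "base::Mersenne-Twister",
                                        .RNG.seed = 99))
  samp <- rjags::coda.samples(mod, c("beta", "sig", "a_men", "a_wom"), 4000)
  ref <- colMeans(as.matrix(samp))

  ours_beta <- tdy$mean[match(paste0("beta[", at$name, "]"), tdy$parameter)]
  expect_lt(max(abs(ours_beta - ref[paste0("beta[", 1:10, "]")])), 0.05)
  ours_sig <- tdy$mean[match(c("sigma[Visual]", "sigma[Default]"),
                             tdy$parameter)]
  expect_lt(max(abs(ours_sig - ref[c("sig[1]", "sig[2]")])), 0.07)
  expect_lt(abs(tdy$mean[tdy$parameter == "alpha_men"] - ref["a_men"]), 0.05)
})

test_that("partial pooling shrinks null coefficients below maximum likelihood", {
  at <- tiny_atlas(c("Visual", "Default"), 5)
  td <- toy_model_data(300, at, rep(0, 10), seed = 21)
  fit <- fit_volume_model(td$X, td$cohort, at, chains = 2, tune = 400,
                          draws = 400, seed = 4)
  post_beta <- tidy(fit)
  post_beta <- post_beta$mean[post_beta$kind == "beta"]
  ml <- glm(td$cohort$loneliness ~ td$X + td$cohort$sex + td$cohort$age_z,
            family = binomial())
  ml_beta <- coef(ml)[paste0("td$X", at$name)]
  expect_lt(mean(abs(post_beta)), mean(abs(ml_beta)))
})

test_that("region- and network-level models agree with one region per network", {
  at7 <- tiny_atlas(canonical_networks(), 1)  # 7 regions, 7 networks
  td <- toy_model_data(400, at7, c(0.5, 0, -0.3, 0, 0.2, 0, 0), seed = 31)
  fr <- fit_volume_model(td$X, td$cohort, at7, model = "region", chains = 2,
                         tune = 600, draws = 600, seed = 5)
  fn <- fit_volume_model(td$X, td$cohort, at7, model = "network", chains = 2,
                         tune = 600, draws = 600, seed = 6)
  br <- tidy(fr); bn <- tidy(fn)
  expect_lt(max(abs(br$mean[br$kind == "beta"] - bn$mean[bn$kind == "beta"])),
            0.05)
})

test_that("prior-predictive prevalence spans (0,1) without degeneracy", {
  set.seed(55)
  at <- load_atlas()
  X <- standardize(matrix(rnorm(300 * 100), 300, 100))
  sims <- replicate(200, {
    sig <- abs(rnorm(7))
    beta <- rnorm(100, 0, sig[at$network_index])
    alpha <- rnorm(2)
    p <- plogis(drop(X %*% beta) + alpha[1])
    c(prev = mean(p), pmin = min(p), pmax = max(p))
  })
  prev <- sims["prev", ]
  # cohort prevalence is spread out, not collapsed to a point ...
  expect_true(all(prev > 0 & prev < 1))
  expect_gt(sd(prev), 0.02)
  expect_gt(diff(range(prev)), 0.15)
  # ... and individual risks reach both ends of (0,1)
  expect_lt(min(sims["pmin", ]), 0.01)
  expect_gt(max(sims["pmax", ]), 0.99)
})

test_that("summaries, ranking and thresholding behave coherently", {
  at <- tiny_atlas(c("Visual", "Default"), 3)
  td <- toy_model_data(250, at, c(0.8, 0, 0, 0, 0, -0.6), seed = 41)
  fit <- fit_volume_model(td$X, td$cohort, at, chains = 2, tune = 300,
                          draws = 300, seed = 8)
  tdy <- tidy(fit)
  # unimodal consistency: mean inside its own HPD interval
  expect_true(all(tdy$hpd_low <= tdy$mean & tdy$mean <= tdy$hpd_high))
  expect_true(all(tdy$rhat > 0.99))

  full <- generate_cohort(generator_config(n = 600, seed = 61))
  cl <- deconfound(full$volumes, full$cohort, character())
  f100 <- fit_volume_model(cl, full$cohort, chains = 2, tune = 200,
                           draws = 200, seed = 9)
  rk <- network_ranking(f100)
  expect_equal(sort(rk$rank), 1:7)
  expect_setequal(rk$network, canonical_networks())
  expect_true(all(diff(rk$sigma_mean) <= 0))

  # thresholding logic on a synthetic summary table
  st <- tibble::tibble(
    parameter = c("beta[a]", "beta[b]", "beta[c]"),
    kind = "beta", group = "pooled",
    region = c("a", "b", "c"), network = "Default",
    mean = c(0.27, 0.05, -0.14),
    hpd_low = c(0.10, -0.10, -0.27),
    hpd_high = c(0.44, 0.20, -0.01),
    rhat = 1, flag = c("positive", "none", "negative"))
  fl <- threshold_regions(st)
  expect_equal(fl$region, c("a", "c"))
  expect_equal(fl$flag, c("positive", "negative"))
})
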