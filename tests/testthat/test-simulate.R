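test_that("region effects follow their network-level scales", {
  at <- load_atlas()
  # degenerate scales: all effects exactly zero
  z <- sample_region_betas(setNames(rep(0, 7), canonical_networks()), at, seed = 1)
  expect_identical(z, rep(0, 100))
  expect_error(sample_region_betas(c(-0.1, rep(0, 6)), at), "non-negative")

  # Monte-Carlo sd oracle: many repeated draws recover sigma per network
  sig <- setNames(c(0.04, 0.04, 0.05, 0.02, 0.06, 0.03, 0.07),
                  canonical_networks())
  set.seed(11)
  draws <- replicate(10000, sample_region_betas(sig, at))
  dn <- which(at$network == "Default")
  sd_default <- sd(as.vector(draws[dn, ]))
  expect_lt(abs(sd_default - 0.07), 0.002)
  sal <- which(at$network == "Salience")
  expect_lt(abs(sd(as.vector(draws[sal, ])) - 0.02), 0.002)

  # determinism
  expect_identical(sample_region_betas(sig, at, seed = 5),
                   sample_region_betas(sig, at, seed = 5))
})

test_that("intercept calibration matches the closed-form logit and is monotone", {
  expect_lt(abs(calibrate_intercept(rep(0, 100), 0.5)), 1e-6)
  # zero predictor: intercept is the log-odds of the target
  expect_lt(abs(calibrate_intercept(rep(0, 50), 0.131) - log(0.131 / 0.869)),
            1e-6)
  set.seed(3)
  eta <- rnorm(200)
  expect_gt(calibrate_intercept(eta, 0.2), calibrate_intercept(eta, 0.1))
  expect_error(calibrate_intercept(c(1, NA), 0.3), "non-finite")
  expect_error(calibrate_intercept(rnorm(5), 1.2), "target")
})

test_that("generated cohorts are reproducible and hit the target prevalence", {
  a <- quick_cohort(n = 800, seed = 99)
  b <- quick_cohort(n = 800, seed = 99)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$fc_edges, b$fc_edges)
  expect_identical(a$fa, b$fa)
  expect_identical(a$cohort, b$cohort)

  # block sub-seeding: volumes identical whether or not fc/fa are generated
  v_only <- generate_cohort(generator_config(n = 800, seed = 99),
                            blocks = "volumes")
  expect_identical(v_only$volumes, a$volumes)
  expect_identical(v_only$cohort$loneliness, a$cohort$loneliness)

  # prevalence lands within binomial noise of the target over several seeds
  prev <- vapply(1:5, function(s) {
    co <- generate_cohort(generator_config(n = 4000, seed = s),
                          blocks = "volumes")
    mean(co$cohort$loneliness)
  }, numeric(1))
  tol <- 3 * sqrt(0.131 * 0.869 / 4000)
  expect_true(all(abs(prev - 0.131) < tol))
})

test_that("a pure-null cohort shows no feature-outcome association", {
  cfg <- generator_config(
    n = 2000, seed = 12,
    sigma_per_network = setNames(rep(0, 7), canonical_networks()),
    fc_mode_strength = 0,
    tract_rho = setNames(rep(0, 48), load_tract_catalog()$tract))
  co <- generate_cohort(cfg)
  bound <- 4 / sqrt(2000)
  y <- co$cohort$loneliness
  expect_lt(max(abs(cor(y, co$volumes))), bound)
  expect_lt(max(abs(cor(y, co$fa))), bound)
  expect_lt(max(abs(cor(y, co$fc_edges[, sample.int(4950, 200)]))), bound)
})

test_that("planted tract correlations are recovered at large n", {
  co <- generate_cohort(generator_config(n = 38701, seed = 4),
                        blocks = c("volumes", "fa"))
  r <- drop(cor(co$cohort$loneliness, co$fa))
  fx <- which(names(r) == "Fornix (column and body)")
  expect_gt(r[fx], 0.05)
  expect_lt(r[fx], 0.07)
  # null tracts stay within sampling error
  expect_lt(max(abs(r[co$truth$tract_rho == 0])), 4 / sqrt(38701))
})

test_that("planted connectivity mode strengthens monotonically with strength", {
  sc <- vapply(c(0, 2, 4), function(s) {
    co <- generate_cohort(generator_config(n = 600, seed = 21,
                                           fc_mode_strength = s))
    proj <- drop(co$fc_edges %*% co$truth$planted_mode)
    cor(proj, co$cohort$loneliness)
  }, numeric(1))
  expect_true(all(diff(sc) > 0))
})

test_that("within-network volume correlation matches the exchangeable target", {
  at <- load_atlas()
  co <- generate_cohort(generator_config(n = 5000, seed = 8),
                        blocks = "volumes")
  dn <- which(at$network == "Default")
  cm <- cor(co$volumes[, dn])
  within <- cm[upper.tri(cm)]
  expect_lt(abs(mean(within) - 0.3), 0.03)
  # across networks uncorrelated by default
  vis <- which(at$network == "Visual")
  expect_lt(max(abs(cor(co$volumes[, dn], co$volumes[, vis])))
            , 4 / sqrt(5000) + 0.02)
})
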