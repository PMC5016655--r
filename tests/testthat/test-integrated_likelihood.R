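# independent fixed-effects Poisson log-likelihood, written term by term
poisson_ll_by_hand <- function(dataset, spec, beta, sigma_det) {
  cp <- dataset$config$cutpoints
  kept <- filter_middens(dataset$events)$events
  kept <- kept[kept$species == spec$species, ]
  b <- bin_distances(kept, cp,
                     transect_ids = dataset$transects$transect_id,
                     species = spec$species)
  Ik <- vapply(seq_len(length(cp) - 1), function(k) integrate(
    function(y) exp(-y^2 / (2 * sigma_det^2)), cp[k], cp[k + 1],
    rel.tol = 1e-12)$value, numeric(1))
  cov <- dataset$covariates
  ll <- 0
  for (i in seq_len(nrow(b))) {
    tr <- dataset$transects[dataset$transects$transect_id ==
                              b$transect_id[i], ]
    x <- cov[cov$transect_id == b$transect_id[i], ]
    eta <- beta[1]
    if (length(beta) > 1)
      eta <- eta + sum(beta[-1] * unlist(x[names(beta)[-1]]))
    lam <- 2 * tr$length_m * exp(eta) * Ik[b$bin[i]]
    ll <- ll + b$count[i] * log(lam) - lam - lgamma(b$count[i] + 1)
  }
  ll
}

test_that("vanishing random effect reduces to the fixed-effects Poisson", {
  ds <- tiny_dataset(n_pairs = 3, n_systems = 2, n_events = 60)
  spec <- integrated_spec("oryx", ~ rock_cover)
  beta <- c("(Intercept)" = -5, rock_cover = 0.01)
  ll_int <- integrated_loglik(ds, spec, c(beta, log(1e-6), log(1.5)))
  ll_fix <- poisson_ll_by_hand(ds, spec, beta, 1.5)
  expect_equal(ll_int, unname(ll_fix), tolerance = 1e-7)
})

test_that("Gauss-Hermite integral matches brute-force integration", {
  # single wadi system so the marginal likelihood is one 1-D integral
  ds <- tiny_dataset(n_pairs = 2, n_systems = 1, n_events = 30, seed = 3)
  spec <- integrated_spec("oryx", ~ rock_cover)
  sigma_b <- 0.4
  theta <- c(-5, 0.01, log(sigma_b), log(1.5))
  ll <- integrated_loglik(ds, spec, theta)

  # trapezoid over b on [-6 sigma_b, 6 sigma_b] with 1e5 points
  cp <- ds$config$cutpoints
  b0 <- bin_distances(filter_middens(ds$events)$events, cp,
                      transect_ids = ds$transects$transect_id,
                      species = "oryx")
  Ik <- vapply(1:3, function(k) integrate(
    function(y) exp(-y^2 / (2 * 1.5^2)), cp[k], cp[k + 1],
    rel.tol = 1e-12)$value, numeric(1))
  cov <- ds$covariates[match(b0$transect_id, ds$covariates$transect_id), ]
  lam0 <- 2 * 200 * exp(-5 + 0.01 * cov$rock_cover) * Ik[b0$bin]
  bgrid <- seq(-6 * sigma_b, 6 * sigma_b, length.out = 1e5)
  h <- vapply(bgrid, function(b)
    sum(b0$count * log(lam0 * exp(b)) - lam0 * exp(b) -
          lgamma(b0$count + 1)) + dnorm(b, 0, sigma_b, log = TRUE),
    numeric(1))
  m <- max(h)
  step <- diff(bgrid)[1]
  ll_bf <- m + log(step * (sum(exp(h - m)) - 0.5 * exp(h[1] - m) -
                             0.5 * exp(h[length(h)] - m)))
  expect_equal(ll, ll_bf, tolerance = 1e-6)
})

test_that("likelihood is invariant to exposure/intercept rescaling", {
  ds <- tiny_dataset(n_pairs = 3, n_systems = 2, n_events = 60)
  spec <- integrated_spec("oryx", ~ rock_cover)
  theta <- c(-5, 0.01, log(0.3), log(1.5))
  ll1 <- integrated_loglik(ds, spec, theta)
  ds2 <- ds
  ds2$transects$length_m <- ds$transects$length_m * 3
  theta2 <- theta
  theta2[1] <- theta[1] - log(3)
  ll2 <- integrated_loglik(ds2, spec, theta2)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("AICc arithmetic and limits", {
  expect_equal(aicc(-100, 3, 36), 206 + 2 * 3 * 4 / 32)
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "n > k")
})

test_that("fitting recovers structure and respects nesting", {
  ds <- simulate_survey(recovery_scenario(), seed = 5)
  f_null <- fit_integrated(ds, integrated_spec("oryx", ~1),
                           fast_options())
  f_rich <- fit_integrated(ds, integrated_spec("oryx", ~ richness),
                           fast_options())
  expect_true(f_null$converged && f_rich$converged)
  expect_gte(f_rich$loglik, f_null$loglik - 1e-6)   # nested consistency
  expect_equal(f_null$k, 3)
  expect_equal(f_rich$k, 4)
  # true effect 0.2 should be found with reasonable accuracy
  expect_lt(abs(f_rich$estimates[["richness"]] - 0.2), 0.1)
  expect_lt(abs(f_rich$estimates[["sigma_det"]] - 1.5), 0.3)

  # doubling the quadrature nodes leaves the optimum unchanged
  ll30 <- integrated_loglik(ds, integrated_spec("oryx", ~ richness),
                            f_rich$theta, nodes = 30)
  expect_equal(f_rich$loglik, ll30, tolerance = 1e-6)

  # interaction model parameter count convention
  f_int <- fit_integrated(ds,
                          integrated_spec("oryx", ~ richness * rock_cover),
                          fast_options())
  expect_equal(f_int$k, 6)
})

test_that("sigma_b truth of zero favors the fixed-effects model", {
  scen <- recovery_scenario()
  scen$species$oryx$sigma_b <- 0
  ds <- simulate_survey(scen, seed = 13)
  spec <- integrated_spec("oryx", ~ richness)
  f_re <- fit_integrated(ds, spec, fast_options())
  f_fix <- fit_integrated(ds, spec, fast_options(random = FALSE))
  expect_true(f_re$diagnostics$sigma_b_boundary ||
                f_re$estimates[["sigma_b"]] < 0.1)
  expect_lte(f_fix$aicc, f_re$aicc + 1e-6)
})

test_that("fixed detection scale matches an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  ds <- simulate_survey(recovery_scenario(), seed = 23)
  spec <- integrated_spec("oryx", ~ richness)
  f <- fit_integrated(ds, spec, fast_options(sigma_det_fixed = 1.5))
  expect_equal(f$k, 3)

  cp <- ds$config$cutpoints
  kept <- filter_middens(ds$events)$events
  b <- bin_distances(kept[kept$species == "oryx", ], cp,
                     transect_ids = ds$transects$transect_id,
                     species = "oryx")
  Ik <- vapply(1:3, function(k) integrate(
    function(y) exp(-y^2 / (2 * 1.5^2)), cp[k], cp[k + 1],
    rel.tol = 1e-12)$value, numeric(1))
  df <- data.frame(
    count = b$count,
    off = log(2 * 200 * Ik[b$bin]),
    richness = ds$covariates$richness[match(b$transect_id,
                                            ds$covariates$transect_id)],
    system = ds$transects$wadi_system[match(b$transect_id,
                                            ds$transects$transect_id)])
  g <- lme4::glmer(count ~ richness + (1 | system) + offset(off),
                   data = df, family = poisson, nAGQ = 15)
  expect_equal(unname(f$estimates[["(Intercept)"]]),
               unname(lme4::fixef(g)[1]), tolerance = 1e-3)
  expect_equal(unname(f$estimates[["richness"]]),
               unname(lme4::fixef(g)[2]), tolerance = 1e-3)
  expect_equal(f$estimates[["sigma_b"]],
               sqrt(unname(lme4::VarCorr(g)$system[1])), tolerance = 5e-3)
})

test_that("density predictions obey the lognormal identities", {
  ds <- simulate_survey(recovery_scenario(), seed = 5)
  f_null <- fit_integrated(ds, integrated_spec("oryx", ~1),
                           fast_options())
  pred <- predict_density(f_null, type = "conditional")
  expect_equal(length(unique(round(pred$density, 12))), 1)  # constant

  pred_m <- predict_density(f_null, type = "marginal")
  expect_equal(pred_m$density / pred$density,
               rep(exp(f_null$estimates[["sigma_b"]]^2 / 2), nrow(pred)),
               tolerance = 1e-9)

  f_rich <- fit_integrated(ds, integrated_spec("oryx", ~ richness),
                           fast_options())
  nd <- data.frame(richness = c(4, 5))
  p <- predict_density(f_rich, nd, type = "conditional")
  expect_equal(p$density[2] / p$density[1],
               exp(f_rich$estimates[["richness"]]), tolerance = 1e-9)
  expect_error(predict_density(f_rich, data.frame(rock_cover = 1)),
               "missing covariate")
})
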