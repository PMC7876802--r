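# Metropolis-within-Gibbs sampler checks: closed-form oracles on tiny
# problems, prior reproduction with the likelihood switched off, and
# structural behaviour of the posterior summaries.

test_that("credible intervals come from posterior quantiles", {
  ps <- structure(list(draws = cbind(gamma = rep(2.5, 100)),
                       summary = data.frame(parameter = "gamma")),
                  class = "posterior_summary")
  expect_equal(credible_interval(ps, "gamma"), c(2.5, 2.5))
  set.seed(5)
  ps2 <- structure(list(draws = cbind(gamma = rnorm(10000))),
                   class = "posterior_summary")
  ci <- credible_interval(ps2, "gamma")
  expect_equal(ci, c(-1.96, 1.96), tolerance = 0.05)
  expect_error(credible_interval(ps2, "nope"), "unknown parameter")
})

test_that("with likelihood off the sampler reproduces its priors", {
  d <- make_tiny_dataset(n = 6, seed = 101)
  # proper test priors with finite moments
  pr <- bayes_priors(v0 = 4, Q = diag(2), v = 4, a = 3, b = 2,
                     lam0_shape = 2, lam0_rate = 2)
  ps <- run_mcmc(d$panel, d$survival, priors = pr,
                 config = mcmc_control(chains = 2, iters = 6000, burnin = 500,
                                       thin = 1, seed = 7),
                 use_likelihood = FALSE)
  g <- ps$draws[, "gamma"]
  expect_lt(abs(mean(g)), 3 * 2 / sqrt(100))       # N(0, 4), ESS >> 100
  expect_lt(abs(stats::var(g) - 4), 0.4)
  s2 <- ps$draws[, "sigma2"]                       # IG(3, 2): mean 1, var 1
  expect_lt(abs(mean(s2) - 1), 0.15)
  l0 <- ps$draws[, "lam0"]                         # Gamma(2, 2): mean 1
  expect_lt(abs(mean(l0) - 1), 0.15)
  # Wishart prior on the precision: E[G] = Q / (v - d - 1) = I (v=4, d=2)
  expect_lt(abs(mean(ps$draws[, "G11"]) - 1), 0.4)
})

test_that("gamma posterior matches a dense-grid posterior on a tiny dataset", {
  d <- make_tiny_dataset(n = 8, seed = 103, gamma = 0.5)
  tr <- d$truth
  truthU <- cbind(tr$U1 - 4.25, tr$U2 - 0.25)   # deviations from the means
  fixv <- list(b0 = 4.25, b1 = 0.25, ba = 0.05, aA = 0.05, aS = -0.5,
               sigma2 = 0.1161, lam0 = 0.02,
               G = matrix(c(0.29, -0.00465, -0.00465, 0.00032), 2, 2),
               U = truthU)
  pr <- bayes_priors()
  ps <- run_mcmc(d$panel, d$survival, priors = pr,
                 config = mcmc_control(chains = 2, iters = 30000,
                                       burnin = 2000, thin = 5, seed = 11),
                 fix = fixv)
  # dense-grid oracle for the 1-D conditional posterior of gamma
  dat <- trajsurv:::.joint_data(d$panel, d$survival)
  loglik_gamma <- function(g) {
    st <- c(fixv, list(gamma = g, U1 = truthU[, 1], U2 = truthU[, 2]))
    sum(trajsurv:::.bs_surv_ll(st, dat)) +
      stats::dnorm(g, 0, sqrt(pr$v0), log = TRUE)
  }
  grid <- seq(-3, 4, length.out = 2001)
  lp <- vapply(grid, loglik_gamma, numeric(1))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  # total variation distance between MCMC histogram and grid posterior
  br <- c(-Inf, grid[-1] - diff(grid)[1] / 2, Inf)
  hist_p <- as.numeric(table(cut(ps$draws[, "gamma"], br))) /
    nrow(ps$draws)
  tv <- sum(abs(hist_p - post)) / 2
  expect_lt(tv, 0.05)
  # credible interval from the same draws brackets the grid-posterior mass
  ci <- credible_interval(ps, "gamma")
  cdf <- cumsum(post)
  ci_grid <- c(grid[which(cdf >= 0.025)[1]], grid[which(cdf >= 0.975)[1]])
  expect_lt(max(abs(ci - ci_grid)), 0.05)
})

test_that("longitudinal-only sampling agrees with the ML mixed-model fit", {
  d <- generate_dataset(gen_params(n = 120, gamma = 0, lam = 1e-12),
                        seed = 107)
  ps <- run_mcmc(d$panel, d$survival,
                 config = mcmc_control(chains = 2, iters = 8000, burnin = 2000,
                                       thin = 2, seed = 13),
                 use_survival = FALSE)
  f <- fit_lme(d$panel)
  s <- ps$summary
  for (pair in list(c("b0", "intercept"), c("b1", "slope"), c("ba", "age"))) {
    post_m <- s$mean[s$parameter == pair[1]]
    post_sd <- s$sd[s$parameter == pair[1]]
    expect_lt(abs(post_m - f$fixed[[pair[2]]]), 2.5 * post_sd)
  }
  expect_lt(abs(s$mean[s$parameter == "sigma2"] - f$sigma2),
            3 * s$sd[s$parameter == "sigma2"])
})

test_that("the gamma posterior contracts as the sample size grows", {
  sds <- vapply(c(40, 160), function(n) {
    p <- gen_params(n = n, gamma = 0.5, lam = 4.2e-6)
    d <- generate_dataset(p, seed = 109)
    ps <- run_mcmc(d$panel, d$survival,
                   config = mcmc_control(chains = 1, iters = 4000,
                                         burnin = 1000, thin = 2, seed = 17))
    ps$summary$sd[ps$summary$parameter == "gamma"]
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("default MCMC configuration mirrors the reference protocol", {
  cfg <- mcmc_control()
  expect_equal(cfg$chains, 4)
  expect_equal(cfg$iters, 101000)
  expect_equal(cfg$burnin, 1000)
  expect_equal(cfg$thin, 50)
})
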