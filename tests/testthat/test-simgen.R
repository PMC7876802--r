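test_that("lambert_w0 satisfies the defining identity and known values", {
  expect_equal(lambert_w0(0), 0)
  expect_equal(lambert_w0(exp(1)), 1, tolerance = 1e-12)
  expect_equal(lambert_w0(1), 0.5671432904097838, tolerance = 1e-12)
  expect_equal(lambert_w0(-exp(-1)), -1)
  expect_error(lambert_w0(-0.5), "principal branch")
  x <- c(10^seq(-8, 6, length.out = 200),
         seq(-exp(-1) + 1e-12, 0, length.out = 200))
  w <- lambert_w0(x)
  expect_lt(max(abs(w * exp(w) - x) / pmax(abs(x), 1e-300)), 1e-10)
  # independent implementation cross-check
  expect_equal(lambert_w0(seq(0.1, 50, by = 0.7)),
               vapply(seq(0.1, 50, by = 0.7), pracma::lambertWp, numeric(1)),
               tolerance = 1e-12)
})

test_that("closed-form survival times invert the plug-in cumulative hazard", {
  # gamma = 0 reduces to the standard Exponential / Weibull inverse CDF
  expect_equal(survival_time_exponential(0, 0, 0, gamma = 0, lam = 1,
                                         M = exp(-2)), 2, tolerance = 1e-12)
  expect_equal(survival_time_weibull(0, 0, 0, gamma = 0, lam = 1, nu = 2,
                                     M = exp(-4)), 2, tolerance = 1e-12)
  # root-finder oracle on the spec's worked cases
  t1 <- survival_time_exponential(0, 1, 0, gamma = 0.2, lam = 0.5, M = 0.5)
  expect_equal(t1, oracle_survival_time(0, 1, 0, 0.2, 0.5, 1, 0.5),
               tolerance = 1e-10)
  expect_equal(t1, 1.110, tolerance = 1e-3)
  t2 <- survival_time_weibull(1, 0.1, 0, gamma = 0.5, lam = 0.1, nu = 1.5,
                              M = 0.5)
  expect_equal(t2, oracle_survival_time(1, 0.1, 0, 0.5, 0.1, 1.5, 0.5),
               tolerance = 1e-8)
  expect_equal(t2, 2.405, tolerance = 1e-3)
  expect_error(survival_time_weibull(0, 0, 0, 0.5, 1, 1.5, M = 1.5), "M must")
})

test_that("closed form matches the root-finding oracle over random draws", {
  set.seed(11)
  n <- 2000
  U1 <- rnorm(n, 4.25, 0.5); U2 <- rnorm(n, 0.25, 0.02)
  xb <- rnorm(n, 0, 1); g <- runif(n, -1, 1)
  lam <- 10^runif(n, -6, -1); nu <- runif(n, 0.5, 2.5); M <- runif(n)
  Tcf <- mapply(function(a, b, x, gg, l, v, m)
    survival_time_weibull(a, b, x, gg, l, v, m), U1, U2, xb, g, lam, nu, M)
  fin <- is.finite(Tcf) & Tcf < 1e7   # oracle brackets up to 1e8
  Tor <- mapply(oracle_survival_time, U1[fin], U2[fin], xb[fin], g[fin],
                lam[fin], nu[fin], M[fin])
  expect_lt(max(abs(Tcf[fin] - Tor) / pmax(Tor, 1e-12)), 1e-8)
  # defining identity on the finite times
  lhs <- lam[fin] * Tcf[fin]^nu[fin] *
    exp(xb[fin] + g[fin] * (U1[fin] + U2[fin] * Tcf[fin]))
  expect_lt(max(abs(lhs + log(M[fin])) / pmax(1, abs(log(M[fin])))), 1e-10)
  # infinite times are genuine: hazard bounded below the target level
  if (any(!fin)) {
    i <- which(!fin)[1]
    expect_lt(g[i] * U2[i], 0)  # only decaying hazards can be unreachable
  }
})

test_that("nu = 1 Weibull reduces exactly to the Exponential inversion", {
  set.seed(3)
  for (k in 1:50) {
    U1 <- rnorm(1); U2 <- rnorm(1, 0, 0.3); xb <- rnorm(1)
    g <- runif(1, -1, 1); lam <- runif(1, 0.001, 1); M <- runif(1)
    expect_identical(survival_time_weibull(U1, U2, xb, g, lam, 1, M),
                     survival_time_exponential(U1, U2, xb, g, lam, M))
  }
})

test_that("survival times are monotone in lam and in gamma*U1", {
  M <- 0.3
  lams <- 10^seq(-5, 0, length.out = 30)
  Ts <- vapply(lams, function(l)
    survival_time_weibull(4, 0.25, 1, 0.5, l, 1.5, M), numeric(1))
  expect_true(all(diff(Ts) <= 0))
  u1s <- seq(2, 6, length.out = 30)
  Ts2 <- vapply(u1s, function(u)
    survival_time_weibull(u, 0.25, 1, 0.5, 1e-4, 1.5, M), numeric(1))
  expect_true(all(diff(Ts2) <= 0))
})

test_that("generate_dataset honours the degenerate noise-free limit", {
  p <- gen_params(n = 20, gamma = 0.3, lam = 1e-5, sigma2 = 0,
                  G = matrix(0, 2, 2))
  d <- generate_dataset(p, seed = 5)
  pred <- p$mu[1] + p$mu[2] * d$panel$time +
    p$beta_age_long * d$panel$age
  expect_equal(d$panel$y, pred, tolerance = 1e-12)
})

test_that("datasets are reproducible and structurally valid", {
  p <- gen_params(n = 60, gamma = 0.5, lam = 2e-5)
  d1 <- generate_dataset(p, seed = 9)
  d2 <- generate_dataset(p, seed = 9)
  expect_identical(d1$panel$y, d2$panel$y)
  expect_identical(d1$survival$time, d2$survival$time)
  expect_identical(d1$truth$S, d2$truth$S)
  validate_pairing(d1$panel, d1$survival)
  m <- table(d1$panel$id)
  expect_true(all(m >= 1 & m <= length(p$exam_times)))
  expect_true(all(d1$survival$time <= p$max_follow + 1e-12))
  # baseline exam always present
  expect_true(all(tapply(d1$panel$time, d1$panel$id, min) == 0))
})

test_that("gamma = 0, nu = 1 event times are exponential given covariates", {
  p <- gen_params(n = 5000, gamma = 0, nu = 1, lam = 0.05,
                  cens_low = 1e5, cens_high = 2e5, max_follow = Inf)
  d <- generate_dataset(p, seed = 21)
  # S * lam * exp(x'beta) is standard Exponential(1)
  xb <- p$alpha_age * d$truth$age + p$alpha_sex * d$truth$sex
  z <- d$truth$S * p$lam * exp(xb)
  ks <- suppressWarnings(stats::ks.test(z, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("lambda calibration hits 10/50/90% censoring targets", {
  p <- gen_params(n = 100, gamma = 0.5)
  for (target in c(0.10, 0.50, 0.90)) {
    lam <- calibrate_lambda(p, target, reps = 4000, seed = 2)
    p2 <- p; p2$lam <- lam
    big <- generate_dataset(gen_params(n = 4000, gamma = 0.5, lam = lam),
                            seed = 77)
    expect_lt(abs(mean(1 - big$survival$event) - target), 0.03)
  }
  # lam -> 0 limit: everything censored
  tiny <- generate_dataset(gen_params(n = 500, gamma = 0.5, lam = 1e-12),
                           seed = 1)
  expect_equal(mean(tiny$survival$event), 0)
})

test_that("calibration agrees with direct quadrature in the gamma = 0 case", {
  # no covariates, no random effects: P(censored) = E_C[ exp(-lam*C) ],
  # C ~ U(25, 30); solve for lam at target 0.5 by 1-D quadrature
  p <- gen_params(n = 100, gamma = 0, nu = 1, G = matrix(0, 2, 2),
                  mu = c(0, 0), alpha_age = 0, alpha_sex = 0,
                  beta_age_long = 0)
  lam_hat <- calibrate_lambda(p, 0.5, reps = 20000, seed = 4)
  pc <- function(lam) stats::integrate(function(c) exp(-lam * c) / 5,
                                       25, 30)$value
  lam_true <- stats::uniroot(function(l) pc(l) - 0.5, c(1e-6, 1))$root
  expect_lt(abs(lam_hat - lam_true) / lam_true, 0.15)
  expect_lt(abs(pc(lam_hat) - 0.5), 0.02)
})
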