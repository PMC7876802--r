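test_that("symmetric tied events give a zero coefficient", {
  tab <- counting_process(data.frame(id = c("a", "b"), start = 0,
                                     stop = c(1, 1), status = 1,
                                     value = c(1, -1)))
  f <- fit_cox_td(tab)
  expect_equal(unname(f$coefficients[["value"]]), 0, tolerance = 1e-8)
})

test_that("three-subject fit matches grid maximization of the partial likelihood", {
  tab <- counting_process(data.frame(id = c("a", "b", "c"), start = 0,
                                     stop = c(1, 2, 3), status = c(1, 1, 0),
                                     value = c(1, 2, 0)))
  # enumerate the 2-term partial likelihood and maximize on a grid
  pl <- function(b) oracle_breslow_loglik(tab, b)
  bgrid <- seq(-3, 3, by = 1e-4)
  b_star <- bgrid[which.max(vapply(bgrid, pl, numeric(1)))]
  f <- fit_cox_td(tab)
  expect_equal(unname(f$coefficients[["value"]]), b_star, tolerance = 1e-3)
  expect_equal(unname(f$coefficients[["value"]]), 0.67, tolerance = 0.02)
  expect_error(fit_cox_td(counting_process(
    data.frame(id = "a", start = 0, stop = 1, status = 0, value = 1))),
    "no events")
})

test_that("fitted log partial likelihood matches brute-force enumeration", {
  d <- generate_dataset(gen_params(n = 25, gamma = 0.5, lam = 2e-5), seed = 31)
  tab <- expand_lvcf(d$panel, d$survival)
  f <- fit_cox_td(tab)
  ll <- oracle_breslow_loglik(tab, f$coefficients)
  expect_equal(f$loglik, ll, tolerance = 1e-10)
  # score is ~0 at the optimum: nudging any coefficient lowers the likelihood
  for (k in seq_along(f$coefficients)) {
    for (eps in c(-1e-4, 1e-4)) {
      b <- f$coefficients; b[k] <- b[k] + eps
      expect_lt(oracle_breslow_loglik(tab, b), ll + 1e-12)
    }
  }
})

test_that("time-constant covariates reduce to the standard right-censored Cox fit", {
  set.seed(41)
  n <- 40
  x <- rnorm(n); T <- rexp(n, 0.2 * exp(0.5 * x)); C <- runif(n, 1, 8)
  tt <- pmin(T, C); d <- as.numeric(T <= C)
  # split each subject's follow-up into two intervals with the same covariate
  tab <- counting_process(data.frame(
    id = rep(seq_len(n), each = 2),
    start = c(rbind(0, tt / 2)), stop = c(rbind(tt / 2, tt)),
    status = c(rbind(0, d)), value = rep(x, each = 2)))
  f1 <- fit_cox_td(tab)
  f2 <- survival::coxph(survival::Surv(tt, d) ~ x, ties = "breslow")
  expect_equal(unname(f1$coefficients[["value"]]), unname(coef(f2)[1]),
               tolerance = 1e-10)
})

test_that("covariate shifts are absorbed by the baseline hazard", {
  d <- generate_dataset(gen_params(n = 50, gamma = 0.5, lam = 2e-5), seed = 37)
  tab <- expand_lvcf(d$panel, d$survival)
  f1 <- fit_cox_td(tab)
  tab2 <- tab; tab2$value <- tab2$value + 10
  f2 <- fit_cox_td(tab2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("LVCF expansion carries values strictly forward and conserves exposure", {
  pan <- long_panel(data.frame(id = "a", time = c(0, 4), y = c(1.5, 2.5),
                               age = 50, sex = 1))
  sv <- surv_records(data.frame(id = "a", time = 7, event = 1))
  tab <- expand_lvcf(pan, sv)
  expect_equal(tab$start, c(0, 4))
  expect_equal(tab$stop, c(4, 7))
  expect_equal(tab$value, c(1.5, 2.5))
  expect_equal(tab$status, c(0, 1))
  # measurement coincident with the event time is not used
  pan2 <- long_panel(data.frame(id = "a", time = c(0, 4, 7),
                                y = c(1.5, 2.5, 9), age = 50, sex = 1))
  tab2 <- expand_lvcf(pan2, sv)
  expect_identical(tab2$value, c(1.5, 2.5))
  expect_equal(max(tab2$stop), 7)
  # missing baseline errors
  pan3 <- long_panel(data.frame(id = "a", time = c(4, 6), y = c(1, 2),
                                age = 50, sex = 1))
  expect_error(expand_lvcf(pan3, sv), "baseline")
  # exposure conservation on simulated data
  d <- generate_dataset(gen_params(n = 80, gamma = 0.5, lam = 2e-5), seed = 43)
  big <- expand_lvcf(d$panel, d$survival)
  exposure <- tapply(big$stop - big$start, big$id, sum)
  expect_equal(as.numeric(exposure[d$survival$id]), d$survival$time,
               tolerance = 1e-12)
})

test_that("predicted-trajectory expansion puts predictions at event times", {
  d <- generate_dataset(gen_params(n = 20, gamma = 0.5, lam = 2e-5), seed = 47)
  f <- fit_lme(d$panel)
  tab <- expand_predicted(f, d$panel, d$survival)
  etimes <- sort(unique(d$survival$time[d$survival$event == 1]))
  # every at-risk subject has an interval ending exactly at each event time,
  # carrying its predicted trajectory value there
  for (te in etimes) {
    at_risk <- d$survival$id[d$survival$time >= te]
    rows <- tab[tab$stop == te & tab$start < te, ]
    expect_setequal(rows$id, at_risk)
    pred <- vapply(rows$id, function(s) predict_trajectory(f, s, te),
                   numeric(1))
    expect_equal(rows$value, unname(pred), tolerance = 1e-10)
  }
  # single event case: every at-risk subject contributes its prediction there
  sv1 <- d$survival
  sv1$event <- as.numeric(seq_len(nrow(sv1)) == which.max(sv1$time * sv1$event))
  tab1 <- expand_predicted(f, d$panel, surv_records(as.data.frame(sv1)))
  t1 <- sv1$time[sv1$event == 1]
  expect_true(all(tab1$stop <= max(d$survival$time)))
  expect_equal(sum(tab1$status), 1)
})

test_that("partial likelihood on the predicted expansion equals direct evaluation", {
  d <- generate_dataset(gen_params(n = 20, gamma = 0.5, lam = 2e-5), seed = 53)
  f <- fit_lme(d$panel)
  tab <- expand_predicted(f, d$panel, d$survival)
  beta <- c(value = 0.4, age = 0.03, sex = -0.3)
  # direct implementation of the partial likelihood with Y*(t) = predicted
  # trajectory, no counting-process machinery
  sv <- d$survival
  base <- unique(as.data.frame(d$panel)[c("id", "age", "sex")])
  ll <- 0
  for (i in which(sv$event == 1)) {
    te <- sv$time[i]
    risk <- sv$id[sv$time >= te]
    eta <- vapply(risk, function(s) {
      b <- base[base$id == s, ]
      beta[["value"]] * predict_trajectory(f, s, te) +
        beta[["age"]] * b$age + beta[["sex"]] * b$sex
    }, numeric(1))
    ll <- ll + eta[[sv$id[i]]] - log(sum(exp(eta)))
  }
  expect_equal(oracle_breslow_loglik(tab, beta), ll, tolerance = 1e-10)
})
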