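# Bayesian shared-parameter joint model with a constant baseline hazard.
#
# Hazard: h(t | U) = lam0 * exp{ aA Age + aS Sex + gamma * [ (b0 + U1) +
# (b1 + U2) t + ba Age ] }; the constant baseline makes the cumulative
# hazard closed-form, so no quadrature is needed in the sampler.
# Sampling: conjugate Gibbs for sigma2 (inverse gamma) and the
# random-effects precision (Wishart); random-walk Metropolis for the fixed
# effects, gamma, alpha, log lam0 and the per-subject random effects (the
# survival factor breaks conjugacy for all of these). Proposal scales adapt
# toward 20-40% acceptance during burn-in only, then freeze.

#' Prior specification for the Bayesian joint model
#'
#' Diffuse defaults: normal(0, v0) on regression-type parameters, Wishart
#' (scale `Q`, df `v`) on the random-effects precision, inverse-gamma on the
#' residual variance and gamma on the constant baseline hazard.
#'
#' @param v0 prior variance of gamma, alpha and the fixed effects.
#' @param Q Wishart scale matrix (the precision prior is Wishart(Q^-1, v)).
#' @param v Wishart degrees of freedom (>= 2).
#' @param a,b inverse-gamma shape/scale for sigma2.
#' @param lam0_shape,lam0_rate gamma prior for the baseline hazard.
#' @return list of class `bayes_priors`.
#' @export
bayes_priors <- function(v0 = 100, Q = diag(2), v = 2, a = 0.01, b = 0.01,
                         lam0_shape = 0.01, lam0_rate = 0.01) {
  stopifnot(v >= 2, a > 0, b > 0, all(eigen(Q, symmetric = TRUE,
                                            only.values = TRUE)$values > 0))
  structure(list(v0 = v0, Q = Q, v = v, a = a, b = b,
                 lam0_shape = lam0_shape, lam0_rate = lam0_rate),
            class = "bayes_priors")
}

#' MCMC run configuration
#'
#' Defaults mirror the reference analysis protocol: 4 chains of 101,000
#' iterations, burn-in 1,000, thinning 50. (With that bookkeeping
#' (101,000 - 1,000) / 50 = 2,000 draws are kept per chain.) Tests and desk
#' runs should pass much smaller values.
#'
#' @param chains,iters,burnin,thin,seed positive integers.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iters = 101000, burnin = 1000,
                         thin = 50, seed = 1) {
  stopifnot(chains >= 1, iters > burnin, thin >= 1)
  structure(list(chains = chains, iters = iters, burnin = burnin,
                 thin = thin, seed = seed), class = "mcmc_control")
}

# closed-form cumulative hazard of the constant-baseline model
.const_cumhaz <- function(lam0, k, cc, T) {
  out <- lam0 * exp(k) * T
  act <- abs(cc) > 1e-12
  out[act] <- lam0 * exp(k[act]) * (exp(cc[act] * T[act]) - 1) / cc[act]
  out
}

# survival log-likelihood per subject (vector)
.bs_surv_ll <- function(st, dat) {
  k <- st$aA * dat$age + st$aS * dat$sex +
    st$gamma * (st$b0 + st$ba * dat$age + st$U1)
  cc <- st$gamma * (st$b1 + st$U2)
  loghaz <- log(st$lam0) + k + cc * dat$T
  dat$delta * loghaz - .const_cumhaz(st$lam0, k, cc, dat$T)
}

# longitudinal log-likelihood per subject (vector), from sufficient stats
.bs_long_ll <- function(st, dat) {
  fe0 <- st$b0 + st$ba * dat$age
  Sd <- dat$Sy - dat$m * fe0 - st$b1 * dat$St
  Sdt <- dat$Syt - fe0 * dat$St - st$b1 * dat$Stt
  Sdd <- dat$Syy - 2 * fe0 * dat$Sy - 2 * st$b1 * dat$Syt +
    dat$m * fe0^2 + 2 * fe0 * st$b1 * dat$St + st$b1^2 * dat$Stt
  SSR <- Sdd - 2 * st$U1 * Sd - 2 * st$U2 * Sdt + st$U1^2 * dat$m +
    2 * st$U1 * st$U2 * dat$St + st$U2^2 * dat$Stt
  -dat$m / 2 * log(2 * pi * st$sigma2) - SSR / (2 * st$sigma2)
}

.bs_ssr_total <- function(st, dat) {
  fe0 <- st$b0 + st$ba * dat$age
  Sd <- dat$Sy - dat$m * fe0 - st$b1 * dat$St
  Sdt <- dat$Syt - fe0 * dat$St - st$b1 * dat$Stt
  Sdd <- dat$Syy - 2 * fe0 * dat$Sy - 2 * st$b1 * dat$Syt +
    dat$m * fe0^2 + 2 * fe0 * st$b1 * dat$St + st$b1^2 * dat$Stt
  sum(Sdd - 2 * st$U1 * Sd - 2 * st$U2 * Sdt + st$U1^2 * dat$m +
        2 * st$U1 * st$U2 * dat$St + st$U2^2 * dat$Stt)
}

#' Metropolis-within-Gibbs sampler for the Bayesian joint model
#'
#' @param panel a [long_panel()].
#' @param survival a [surv_records()].
#' @param priors a [bayes_priors()].
#' @param config an [mcmc_control()].
#' @param use_likelihood set `FALSE` to replace the likelihood by 1 (prior
#'   reproduction smoke test).
#' @param use_survival set `FALSE` to drop the survival factor (conjugate
#'   longitudinal-only sanity checks).
#' @param fix named list of parameters to hold fixed at given values; may
#'   include `U` (an n x 2 matrix of random effects, matched to sorted
#'   subject ids). Fixed parameters are not sampled.
#' @return Object of class `posterior_summary`: `summary` data.frame (mean,
#'   sd, 2.5%/97.5% quantiles, Gelman-Rubin rhat, effective sample size per
#'   parameter), `draws` (kept draws, rows = iterations, stacked chains),
#'   `chain` (chain index per row), `accept` (acceptance rates),
#'   `convergence_warning` flag (rhat for gamma > 1.1).
#' @export
run_mcmc <- function(panel, survival, priors = bayes_priors(),
                     config = mcmc_control(), use_likelihood = TRUE,
                     use_survival = TRUE, fix = list()) {
  dat <- .joint_data(panel, survival)
  n <- dat$n
  pars <- c("b0", "b1", "ba", "gamma", "aA", "aS", "sigma2", "lam0",
            "G11", "G12", "G22")
  Qinv_prior <- solve(priors$Q)

  # initial state from cheap moment fits
  st0 <- list(b0 = mean(dat$Sy / dat$m), b1 = 0, ba = 0, gamma = 0,
              aA = 0, aS = 0, sigma2 = 1,
              lam0 = max(sum(dat$delta) / max(sum(dat$T), 1), 1e-6),
              U1 = rep(0, n), U2 = rep(0, n),
              Ginv = diag(c(1, 10)))
  free <- function(nm) !(nm %in% names(fix))
  for (nm in intersect(names(fix), c("b0","b1","ba","gamma","aA","aS",
                                     "sigma2","lam0")))
    st0[[nm]] <- fix[[nm]]
  if ("G" %in% names(fix)) st0$Ginv <- solve(fix$G)
  if ("U" %in% names(fix)) { st0$U1 <- fix$U[, 1]; st0$U2 <- fix$U[, 2] }

  rw_pars <- c("b0", "b1", "ba", "gamma", "aA", "aS", "loglam0")
  keep_per <- floor((config$iters - config$burnin) / config$thin)
  all_draws <- vector("list", config$chains)
  acc_all <- NULL

  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    st <- st0
    # chain overdispersion on free regression-type parameters
    for (nm in c("b0", "b1", "gamma")) if (free(nm))
      st[[nm]] <- st[[nm]] + stats::rnorm(1, 0, 0.2)
    scales <- c(b0 = 0.1, b1 = 0.02, ba = 0.01, gamma = 0.1, aA = 0.02,
                aS = 0.2, loglam0 = 0.3)
    u_scale <- c(0.3, 0.05)
    acc <- stats::setNames(numeric(length(rw_pars)), rw_pars)
    prop <- acc; acc_u <- 0; prop_u <- 0
    draws <- matrix(NA_real_, keep_per, length(pars),
                    dimnames = list(NULL, pars))
    kept <- 0L

    log_post_globals <- function(st) {
      lp <- 0
      if (use_likelihood) {
        lp <- lp + sum(.bs_long_ll(st, dat))
        if (use_survival) lp <- lp + sum(.bs_surv_ll(st, dat))
      }
      lp +
        sum(stats::dnorm(c(st$b0, st$b1, st$ba, st$gamma, st$aA, st$aS),
                         0, sqrt(priors$v0), log = TRUE)) +
        stats::dgamma(st$lam0, priors$lam0_shape, priors$lam0_rate, log = TRUE) +
        log(st$lam0)        # Jacobian: RW on log lam0
    }

    for (it in seq_len(config$iters)) {
      # -- RW Metropolis on global regression-type parameters
      lp_cur <- log_post_globals(st)
      for (nm in rw_pars) {
        target <- if (nm == "loglam0") "lam0" else nm
        if (!free(target)) next
        if (!use_survival && target %in% c("gamma", "aA", "aS", "lam0")) next
        cand <- st
        if (nm == "loglam0") cand$lam0 <- exp(log(st$lam0) +
                                                stats::rnorm(1, 0, scales[[nm]]))
        else cand[[nm]] <- st[[nm]] + stats::rnorm(1, 0, scales[[nm]])
        prop[[nm]] <- prop[[nm]] + 1
        lp_cand <- log_post_globals(cand)
        if (log(stats::runif(1)) < lp_cand - lp_cur) {
          st <- cand; lp_cur <- lp_cand; acc[[nm]] <- acc[[nm]] + 1
        }
      }
      # -- per-subject random effects, 2-D RW (independent across subjects)
      if (free("U")) {
        prop_u <- prop_u + 1
        cU1 <- st$U1 + stats::rnorm(n, 0, u_scale[1])
        cU2 <- st$U2 + stats::rnorm(n, 0, u_scale[2])
        lp_cur <- .bs_u_logpost(st, dat, st$U1, st$U2, use_likelihood,
                                use_survival)
        lp_new <- .bs_u_logpost(st, dat, cU1, cU2, use_likelihood,
                                use_survival)
        take <- log(stats::runif(n)) < lp_new - lp_cur
        st$U1[take] <- cU1[take]; st$U2[take] <- cU2[take]
        acc_u <- acc_u + mean(take)
      }
      # -- conjugate blocks
      if (free("sigma2") && use_likelihood) {
        ssr <- .bs_ssr_total(st, dat)
        st$sigma2 <- 1 / stats::rgamma(1, priors$a + sum(dat$m) / 2,
                                       priors$b + ssr / 2)
      } else if (free("sigma2")) {
        st$sigma2 <- 1 / stats::rgamma(1, priors$a, priors$b)
      }
      if (free("G")) {
        S <- if (use_likelihood)
          crossprod(cbind(st$U1, st$U2)) else matrix(0, 2, 2)
        df <- priors$v + if (use_likelihood) n else 0
        st$Ginv <- stats::rWishart(1, df, solve(priors$Q + S))[, , 1]
      }
      # -- burn-in adaptation toward 20-40% acceptance
      if (it <= config$burnin && it %% 50 == 0) {
        rate <- ifelse(prop > 0, acc / prop, 0.3)
        scales <- pmin(pmax(scales * exp(rate - 0.3), 1e-4), 10)
        if (prop_u > 0) {
          u_scale <- pmin(pmax(u_scale * exp(acc_u / prop_u - 0.3), 1e-5), 5)
        }
        acc[] <- 0; prop[] <- 0; acc_u <- 0; prop_u <- 0
      }
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0 &&
          kept < keep_per) {
        kept <- kept + 1L
        G <- solve(st$Ginv)
        draws[kept, ] <- c(st$b0, st$b1, st$ba, st$gamma, st$aA, st$aS,
                           st$sigma2, st$lam0, G[1, 1], G[1, 2], G[2, 2])
      }
    }
    all_draws[[ch]] <- draws[seq_len(kept), , drop = FALSE]
    rates <- c(ifelse(prop > 0, acc / prop, NA), u = if (prop_u) acc_u / prop_u else NA)
    acc_all <- rbind(acc_all, rates)
  }

  D <- do.call(rbind, all_draws)
  chain <- rep(seq_len(config$chains), vapply(all_draws, nrow, integer(1)))
  summ <- data.frame(parameter = pars,
                     mean = colMeans(D),
                     sd = apply(D, 2, stats::sd),
                     q2.5 = apply(D, 2, stats::quantile, 0.025),
                     q97.5 = apply(D, 2, stats::quantile, 0.975),
                     rhat = vapply(pars, function(p)
                       .gelman_rhat(D[, p], chain), numeric(1)),
                     ess = vapply(pars, function(p)
                       .ess(D[, p], chain), numeric(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
  warn <- is.finite(summ$rhat[summ$parameter == "gamma"]) &&
    summ$rhat[summ$parameter == "gamma"] > 1.1
  structure(list(summary = summ, draws = D, chain = chain,
                 accept = acc_all, chains = config$chains,
                 convergence_warning = warn),
            class = "posterior_summary")
}

# per-subject log posterior factor involving U (up to constants)
.bs_u_logpost <- function(st, dat, U1, U2, use_likelihood, use_survival) {
  s <- st; s$U1 <- U1; s$U2 <- U2
  lp <- -(st$Ginv[1, 1] * U1^2 + 2 * st$Ginv[1, 2] * U1 * U2 +
            st$Ginv[2, 2] * U2^2) / 2
  if (use_likelihood) {
    lp <- lp + .bs_long_ll(s, dat)
    if (use_survival) lp <- lp + .bs_surv_ll(s, dat)
  }
  lp
}

.gelman_rhat <- function(x, chain) {
  ch <- split(x, chain)
  ch <- ch[vapply(ch, length, integer(1)) > 1]
  if (length(ch) < 2) return(NA_real_)
  m <- length(ch); n <- min(lengths(ch))
  ch <- lapply(ch, utils::head, n)
  means <- vapply(ch, mean, numeric(1))
  vars <- vapply(ch, stats::var, numeric(1))
  B <- n * stats::var(means); W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(x, chain) {
  per <- vapply(split(x, chain), function(v) {
    if (length(v) < 10 || stats::sd(v) == 0) return(length(v))
    ac <- stats::acf(v, plot = FALSE, lag.max = min(100, length(v) - 1))$acf[-1]
    pos <- which(ac < 0.05)
    s <- if (length(pos)) sum(ac[seq_len(pos[1] - 1)]) else sum(ac)
    length(v) / (1 + 2 * max(s, 0))
  }, numeric(1))
  sum(per)
}

#' Equal-tailed 95% credible interval
#'
#' @param summary a [run_mcmc()] result.
#' @param parameter parameter name (one of the rows of `summary$summary`).
#' @return numeric `c(low, high)` from the 2.5% and 97.5% posterior
#'   quantiles.
#' @export
credible_interval <- function(summary, parameter) {
  stopifnot(inherits(summary, "posterior_summary"))
  if (!parameter %in% colnames(summary$draws))
    stop("unknown parameter: ", parameter)
  unname(stats::quantile(summary$draws[, parameter], c(0.025, 0.975)))
}

#' One-call Bayesian joint-model estimator
#'
#' @inheritParams run_mcmc
#' @return A `method_result` with method `"BSJM"`; `gamma_hat` is the
#'   posterior mean, `ci95` the equal-tailed credible interval and
#'   `gamma_se` the posterior SD.
#' @export
fit_bsjm <- function(panel, survival, priors = bayes_priors(),
                     config = mcmc_control()) {
  ps <- run_mcmc(panel, survival, priors = priors, config = config)
  s <- ps$summary
  g <- function(p, col) s[[col]][s$parameter == p]
  structure(list(method = "BSJM",
                 gamma_hat = g("gamma", "mean"), gamma_se = g("gamma", "sd"),
                 alpha_age_hat = g("aA", "mean"), alpha_age_se = g("aA", "sd"),
                 alpha_sex_hat = g("aS", "mean"), alpha_sex_se = g("aS", "sd"),
                 ci95 = credible_interval(ps, "gamma"),
                 loglik = NA_real_,
                 converged = !ps$convergence_warning, posterior = ps),
            class = "method_result")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$chains, "chains,", nrow(x$draws),
      "kept draws )\n")
  print(x$summary, digits = 4)
  if (x$convergence_warning)
    cat("warning: Gelman-Rubin rhat for gamma exceeds 1.1\n")
  invisible(x)
}
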