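# Simulation-study harness: scenario cells over distribution x n x censoring
# x gamma x sigma2, replicate management with deterministic per-replicate
# seeds, and the aggregate metrics (Type I error, mean estimate, model SE,
# empirical SD, coverage, bias, MSE).

#' Define a simulation-study scenario
#'
#' @param distribution `"weibull"` or `"exponential"` (the latter fixes
#'   nu = 1).
#' @param n subjects per replicate.
#' @param censoring_target target censoring fraction in (0, 1); the baseline
#'   scale lambda is calibrated once per scenario via [calibrate_lambda()].
#' @param gamma_true true link parameter.
#' @param sigma2 residual variance of the longitudinal measurements.
#' @param nu Weibull shape used when `distribution = "weibull"`.
#' @param replicates number of Monte-Carlo replicates.
#' @param seed scenario seed; replicate r uses seed + r.
#' @param methods subset of `c("TSA", "TDCM", "MLA", "BSJM")`.
#' @param generation_scheme `"table1"` (closed-form plug-in-hazard
#'   inversion) or `"rizopoulos"` (numerical inversion of the integrated
#'   hazard of the fitting model).
#' @param joint_ctrl a [joint_control()] for the MLA fits.
#' @param bayes_config an [mcmc_control()] for the BSJM fits.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(distribution = c("weibull", "exponential"),
                            n = 100, censoring_target = 0.1,
                            gamma_true = 0.5, sigma2 = 0.1161, nu = 1.5,
                            replicates = 100, seed = 1,
                            methods = c("TSA", "TDCM"),
                            generation_scheme = c("table1", "rizopoulos"),
                            joint_ctrl = joint_control(se = TRUE),
                            bayes_config = mcmc_control(chains = 2,
                                                        iters = 4000,
                                                        burnin = 1000,
                                                        thin = 5)) {
  distribution <- match.arg(distribution)
  generation_scheme <- match.arg(generation_scheme)
  stopifnot(replicates >= 1, censoring_target > 0, censoring_target < 1,
            all(methods %in% c("TSA", "TDCM", "MLA", "BSJM")))
  structure(list(distribution = distribution, n = n,
                 censoring_target = censoring_target,
                 gamma_true = gamma_true, sigma2 = sigma2,
                 nu = if (distribution == "exponential") 1 else nu,
                 replicates = replicates, seed = seed, methods = methods,
                 generation_scheme = generation_scheme,
                 joint_ctrl = joint_ctrl, bayes_config = bayes_config),
            class = "scenario_config")
}

#' Two-sided Wald rejection of gamma = 0 at the 5% level
#'
#' @param gamma_hat point estimate.
#' @param se standard error (> 0).
#' @param level significance level.
#' @return 1 if |gamma_hat / se| exceeds the normal quantile, else 0.
#' @export
wald_reject <- function(gamma_hat, se, level = 0.05) {
  stopifnot(all(se > 0))
  as.numeric(abs(gamma_hat / se) > stats::qnorm(1 - level / 2))
}

#' 95% Wald-interval coverage indicator
#'
#' @param gamma_hat point estimate.
#' @param se standard error (> 0).
#' @param gamma_true true value.
#' @return 1 if gamma_true lies in gamma_hat +/- 1.96 se, else 0.
#' @export
coverage <- function(gamma_hat, se, gamma_true) {
  stopifnot(all(se > 0))
  as.numeric(gamma_true >= gamma_hat - 1.96 * se &
               gamma_true <= gamma_hat + 1.96 * se)
}

.scenario_params <- function(config, lam) {
  gen_params(n = config$n, gamma = config$gamma_true, lam = lam,
             nu = config$nu, sigma2 = config$sigma2,
             scheme = config$generation_scheme)
}

#' Calibrated baseline scale for a scenario
#' @param config a [scenario_config()].
#' @param reps calibration Monte-Carlo size.
#' @return lambda hitting the scenario's censoring target.
#' @export
scenario_lambda <- function(config, reps = 5000) {
  calibrate_lambda(.scenario_params(config, lam = 1), config$censoring_target,
                   reps = reps, seed = config$seed)
}

#' Run one simulation-study scenario
#'
#' Per replicate r, data are generated with seed `seed + r` and every
#' requested method is fitted; aggregates are computed over converged fits
#' only (with the non-converged count reported).
#'
#' @param config a [scenario_config()].
#' @param lam optional pre-calibrated baseline scale (computed via
#'   [scenario_lambda()] when omitted).
#' @return Object of class `study_result`: `metrics` (data.frame per method
#'   with mean_estimate, mean_model_se, empirical_sd, cp, bias, mse, type1,
#'   n_converged), `replicates` (tidy per-replicate data.frame) and the
#'   config.
#' @export
run_scenario <- function(config, lam = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(lam)) lam <- scenario_lambda(config)
  params <- .scenario_params(config, lam)
  rows <- vector("list", config$replicates * length(config$methods))
  k <- 0L
  for (r in seq_len(config$replicates)) {
    dset <- generate_dataset(params, seed = config$seed + r)
    for (m in config$methods) {
      fit <- tryCatch(switch(m,
        TSA  = fit_tsa(dset$panel, dset$survival),
        TDCM = fit_tdcm(dset$panel, dset$survival),
        MLA  = fit_mla(dset$panel, dset$survival, control = config$joint_ctrl),
        BSJM = fit_bsjm(dset$panel, dset$survival,
                        config = config$bayes_config)),
        error = function(e) NULL)
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = r, method = m,
        gamma_hat = if (is.null(fit)) NA_real_ else fit$gamma_hat,
        gamma_se = if (is.null(fit)) NA_real_ else fit$gamma_se,
        ci_low = if (is.null(fit)) NA_real_ else fit$ci95[1],
        ci_high = if (is.null(fit)) NA_real_ else fit$ci95[2],
        converged = if (is.null(fit)) FALSE else isTRUE(fit$converged),
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  metrics <- do.call(rbind, lapply(config$methods, function(m) {
    d <- reps[reps$method == m & reps$converged &
                is.finite(reps$gamma_hat) & is.finite(reps$gamma_se) &
                reps$gamma_se > 0, , drop = FALSE]
    R <- nrow(d)
    if (R == 0)
      return(data.frame(method = m, mean_estimate = NA_real_,
                        mean_model_se = NA_real_, empirical_sd = NA_real_,
                        cp = NA_real_, bias = NA_real_, mse = NA_real_,
                        type1 = NA_real_, n_converged = 0L, failed = TRUE))
    if (m == "BSJM") {
      cov <- as.numeric(config$gamma_true >= d$ci_low &
                          config$gamma_true <= d$ci_high)
      rej <- as.numeric(0 < d$ci_low | 0 > d$ci_high)
    } else {
      cov <- coverage(d$gamma_hat, d$gamma_se, config$gamma_true)
      rej <- wald_reject(d$gamma_hat, d$gamma_se)
    }
    data.frame(method = m,
               mean_estimate = mean(d$gamma_hat),
               mean_model_se = mean(d$gamma_se),
               empirical_sd = if (R > 1) stats::sd(d$gamma_hat) else NA_real_,
               cp = mean(cov),
               bias = mean(d$gamma_hat) - config$gamma_true,
               mse = mean((d$gamma_hat - config$gamma_true)^2),
               type1 = if (config$gamma_true == 0) mean(rej) else NA_real_,
               n_converged = R, failed = FALSE)
  }))
  structure(list(metrics = metrics, replicates = reps, config = config,
                 lam = lam), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Scenario: %s, n=%d, censoring %.0f%%, gamma=%.3f, sigma2=%.4f, R=%d (%s)\n",
    cfg$distribution, cfg$n, 100 * cfg$censoring_target, cfg$gamma_true,
    cfg$sigma2, cfg$replicates, cfg$generation_scheme))
  print(x$metrics, digits = 4, row.names = FALSE)
  invisible(x)
}
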