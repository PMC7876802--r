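# Stage-one longitudinal model: random-intercept/random-slope Gaussian LMM
#   Y_ij = (b0 + U1_i) + (b1 + U2_i) t_ij + b_age Age_i + e_ij
# fit by maximum likelihood (lme4, Cholesky-parameterized covariance with
# profiled fixed effects), with empirical-Bayes (BLUP) prediction of the
# subject-specific trajectories used by the two-step estimator.

#' Fit the linear mixed model to a longitudinal panel
#'
#' @param panel a [long_panel()].
#' @param include_age include baseline age as a fixed covariate (default TRUE,
#'   matching the generating trajectory).
#' @param reml use REML instead of ML (default FALSE: ML, consistent with the
#'   joint model's likelihood).
#' @return An object of class `lme_fit`: list with `fixed` (named vector
#'   intercept/slope/age), `G` (2x2 random-effects covariance), `sigma2`,
#'   `blups` (data.frame id, b1, b2 of random-effect deviations), `loglik`,
#'   `vcov_fixed`, `ages` (named per-subject baseline ages), `converged`,
#'   and the underlying `lme4` fit in `model`.
#' @export
fit_lme <- function(panel, include_age = TRUE, reml = FALSE) {
  stopifnot(inherits(panel, "long_panel"))
  if (length(unique(panel$id)) < 2) stop("need at least 2 subjects")
  if (length(unique(panel$time)) < 2) stop("need at least 2 distinct times")
  df <- as.data.frame(panel)
  form <- if (include_age) y ~ time + age + (time | id) else y ~ time + (time | id)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  fe <- lme4::fixef(fit)
  # a constant age column is rank-deficient and silently dropped by lmer
  fe_age <- if (include_age && "age" %in% names(fe)) unname(fe[["age"]]) else 0
  fixed <- c(intercept = unname(fe[["(Intercept)"]]),
             slope = unname(fe[["time"]]), age = fe_age)
  vc <- lme4::VarCorr(fit)
  G <- matrix(as.numeric(vc$id)[1:4], 2, 2)
  re <- lme4::ranef(fit)$id
  blups <- data.frame(id = rownames(re), b1 = re[["(Intercept)"]],
                      b2 = re[["time"]], stringsAsFactors = FALSE)
  ages <- tapply(df$age, df$id, `[`, 1)
  conv <- is.null(fit@optinfo$conv$lme4$code)
  structure(list(fixed = fixed, G = G, sigma2 = stats::sigma(fit)^2,
                 blups = blups, loglik = as.numeric(stats::logLik(fit)),
                 vcov_fixed = as.matrix(stats::vcov(fit)),
                 ages = ages, include_age = include_age,
                 converged = conv, model = fit),
            class = "lme_fit")
}

#' Empirical-Bayes random-effect predictions
#'
#' Returns the conditional means \eqn{b_i = G Z_i' V_i^{-1} (y_i - X_i\beta)}
#' of the subject random effects given the data ("BLUPs").
#'
#' @param fit an [fit_lme()] result.
#' @param ids optional character vector of subject ids (default: all).
#' @return data.frame with columns id, b1 (intercept deviation), b2 (slope
#'   deviation).
#' @export
predict_blups <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "lme_fit"))
  b <- fit$blups
  if (is.null(ids)) return(b)
  i <- match(as.character(ids), b$id)
  if (anyNA(i)) stop("unknown subject id(s): ",
                     paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  b[i, , drop = FALSE]
}

#' Predicted subject-specific trajectory value
#'
#' Evaluates \eqn{(\beta_0 + b_{1i}) + (\beta_1 + b_{2i}) t + \beta_{age}
#' Age_i} at arbitrary times, including beyond the subject's last exam.
#'
#' @param fit an [fit_lme()] result.
#' @param id single subject id.
#' @param t numeric vector of times (years).
#' @return Numeric vector of predicted trajectory values.
#' @export
predict_trajectory <- function(fit, id, t) {
  b <- predict_blups(fit, id)
  age <- fit$ages[[as.character(id)]]
  (fit$fixed[["intercept"]] + b$b1) + (fit$fixed[["slope"]] + b$b2) * t +
    fit$fixed[["age"]] * age
}

# All-subjects trajectory matrix evaluated at a vector of times; rows follow
# fit$blups order. Internal fast path for the risk-set expansion.
.trajectory_matrix <- function(fit, times) {
  b <- fit$blups
  age <- as.numeric(fit$ages[b$id])
  int <- fit$fixed[["intercept"]] + b$b1 + fit$fixed[["age"]] * age
  slo <- fit$fixed[["slope"]] + b$b2
  outer(slo, times) + int
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("Linear mixed model (ML) fit:", nrow(x$blups), "subjects\n")
  cat("fixed effects:", paste(sprintf("%s=%.4f", names(x$fixed), x$fixed),
                              collapse = ", "), "\n")
  cat(sprintf("sigma2=%.5f  G11=%.5f G12=%.6f G22=%.6f  loglik=%.2f\n",
              x$sigma2, x$G[1, 1], x$G[1, 2], x$G[2, 2], x$loglik))
  invisible(x)
}
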