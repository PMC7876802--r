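# Time-dependent Cox engine on counting-process data, plus the two risk-set
# expansions used by the estimators: last-value-carried-forward over observed
# measurements, and event-time breakpoints carrying model-predicted
# trajectory values.

#' Fit a Cox model on a counting-process table
#'
#' Maximizes the partial likelihood with Breslow handling of ties
#' (Newton-Raphson, survival package engine). Standard errors are Wald SEs
#' from the inverse observed information.
#'
#' @param table a [counting_process()] table; every column other than
#'   id/start/stop/status enters as a covariate.
#' @param ties tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit`: `coefficients`, `se`, `information`,
#'   `loglik`, `iterations`, `converged`, and the `survival::coxph` fit in
#'   `model`.
#' @export
fit_cox_td <- function(table, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  table <- counting_process(as.data.frame(table))
  if (sum(table$status) < 1) stop("no events in counting-process table")
  covs <- setdiff(names(table), c("id", "start", "stop", "status"))
  if (!length(covs)) stop("no covariate columns")
  form <- stats::as.formula(paste("survival::Surv(start, stop, status) ~",
                                  paste(covs, collapse = " + ")))
  fit <- suppressWarnings(
    survival::coxph(form, data = as.data.frame(table), ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)))
  info <- solve(stats::vcov(fit))
  conv <- is.finite(fit$loglik[2]) && all(is.finite(coef(fit))) &&
    fit$iter < 50
  structure(list(coefficients = stats::coef(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 information = info,
                 loglik = fit$loglik[2],
                 iterations = fit$iter,
                 converged = conv,
                 model = fit),
            class = "cox_fit")
}

#' Last-value-carried-forward counting-process expansion
#'
#' Builds one (start, stop] row per measurement interval, carrying the most
#' recent observed value `Y_ij` forward until the next measurement; the final
#' interval ends at the observed follow-up time with the event status.
#' A measurement coincident with the follow-up time is not used (strict
#' carry-forward).
#'
#' @param panel a [long_panel()] (each subject must have a baseline
#'   measurement at t = 0).
#' @param survival a [surv_records()].
#' @return A [counting_process()] table with covariates value, age, sex.
#' @export
expand_lvcf <- function(panel, survival) {
  validate_pairing(panel, survival)
  sp <- split(as.data.frame(panel), panel$id)
  Tt <- stats::setNames(survival$time, survival$id)
  dd <- stats::setNames(survival$event, survival$id)
  rows <- lapply(sp, function(d) {
    id <- d$id[1]
    if (d$time[1] != 0) stop("subject ", id, " lacks a baseline measurement at t = 0")
    Ti <- Tt[[id]]
    d <- d[d$time < Ti, , drop = FALSE]     # strict carry-forward
    k <- nrow(d)
    start <- d$time
    stop_ <- c(d$time[-1], Ti)
    data.frame(id = id, start = start, stop = stop_,
               status = c(rep(0, k - 1), dd[[id]]),
               value = d$y, age = d$age[1], sex = d$sex[1],
               stringsAsFactors = FALSE)
  })
  counting_process(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Event-time counting-process expansion with predicted trajectories
#'
#' Breaks follow-up at every distinct event time, so each risk set sees every
#' at-risk subject's model-predicted trajectory value evaluated at that event
#' time (the covariate on each interval is the prediction at the interval's
#' stop time).
#'
#' @param fit an [fit_lme()] result (must be converged).
#' @param panel a [long_panel()] (used for baseline covariates).
#' @param survival a [surv_records()].
#' @return A [counting_process()] table with covariates value, age, sex.
#' @export
expand_predicted <- function(fit, panel, survival) {
  stopifnot(inherits(fit, "lme_fit"))
  if (!fit$converged) stop("LME fit did not converge")
  etimes <- sort(unique(survival$time[survival$event == 1]))
  base <- unique(as.data.frame(panel)[c("id", "age", "sex")])
  ord <- match(fit$blups$id, base$id)
  if (anyNA(ord)) stop("panel/fit subject mismatch")
  base <- base[ord, , drop = FALSE]
  sv <- survival[match(base$id, survival$id), , drop = FALSE]
  n <- nrow(base)
  # subject-specific predicted line: intercept + slope * t
  int <- fit$fixed[["intercept"]] + fit$blups$b1 + fit$fixed[["age"]] * base$age
  slo <- fit$fixed[["slope"]] + fit$blups$b2
  cnt <- vapply(sv$time, function(T) sum(etimes < T), integer(1))
  k <- cnt + 1L
  idx <- rep(seq_len(n), k)
  stop_ <- unlist(lapply(seq_len(n), function(i)
    c(etimes[seq_len(cnt[i])], sv$time[i])), use.names = FALSE)
  start_ <- c(0, stop_[-length(stop_)])
  start_[cumsum(c(1L, k[-n]))] <- 0            # first row of each subject
  status <- numeric(length(stop_))
  status[cumsum(k)] <- sv$event                # last row of each subject
  counting_process(data.frame(id = base$id[idx], start = start_, stop = stop_,
                              status = status,
                              value = int[idx] + slo[idx] * stop_,
                              age = base$age[idx], sex = base$sex[idx],
                              stringsAsFactors = FALSE))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Time-dependent Cox fit (Breslow ties)\n")
  print(data.frame(coef = x$coefficients, se = x$se))
  cat(sprintf("loglik=%.3f  iterations=%d  converged=%s\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}
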