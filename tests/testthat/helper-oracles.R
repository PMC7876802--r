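# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check: the partial likelihood is
# enumerated directly over risk sets, survival times are recovered by
# one-dimensional root finding, and joint likelihood contributions are
# integrated on a dense 2-D grid.

# Breslow log partial likelihood for a counting-process table, by direct
# enumeration: risk set at event time t = rows with start < t <= stop.
oracle_breslow_loglik <- function(table, beta) {
  covs <- setdiff(names(table), c("id", "start", "stop", "status"))
  X <- as.matrix(table[covs])
  eta <- drop(X %*% beta)
  ev <- which(table$status == 1)
  ll <- 0
  for (e in ev) {
    t_e <- table$stop[e]
    risk <- table$start < t_e & t_e <= table$stop
    ll <- ll + eta[e] - log(sum(exp(eta[risk])))
  }
  ll
}

# Solve lam * T^nu * exp(xbeta + gamma*(U1 + U2*T)) = -log(M) by root
# bracketing (independent of the Lambert-W closed form).
oracle_survival_time <- function(U1, U2, xbeta, gamma, lam, nu, M) {
  target <- -log(M)
  H <- function(t) lam * t^nu * exp(xbeta + gamma * (U1 + U2 * t))
  if (gamma * U2 < 0) {
    # H rises to a peak at t* = -nu/(gamma*U2) then decays; the first
    # crossing (if any) lies in (0, t*]
    hi <- -nu / (gamma * U2)
    if (H(hi) < target) return(Inf)
  } else {
    hi <- 1
    while (H(hi) < target && hi < 1e8) hi <- hi * 2
    if (H(hi) < target) return(Inf)
  }
  stats::uniroot(function(t) H(t) - target, c(0, hi), tol = 1e-13)$root
}

# One subject's joint likelihood contribution by dense 2-D trapezoid
# integration over the random effects, with the cumulative hazard from
# stats::integrate. `p` uses the joint_loglik parameter list.
oracle_joint_contrib <- function(p, y, tobs, Tt, delta, age, sex,
                                 half_width = 6, grid_n = 401) {
  sd1 <- sqrt(p$G[1, 1]); sd2 <- sqrt(p$G[2, 2])
  u1 <- seq(-half_width * sd1, half_width * sd1, length.out = grid_n)
  u2 <- seq(-half_width * sd2, half_width * sd2, length.out = grid_n)
  Ginv <- solve(p$G)
  fe <- p$fixed[[1]] + p$fixed[[2]] * tobs + p$fixed[[3]] * age
  eta <- p$alpha_age * age + p$alpha_sex * sex +
    p$gamma * (p$fixed[[1]] + p$fixed[[3]] * age)
  vals <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    U1 <- u1[i]; U2 <- u2[j]
    ll_long <- sum(stats::dnorm(y, fe + U1 + U2 * tobs,
                                sqrt(p$sigma2), log = TRUE))
    ll_prior <- -log(2 * pi) - 0.5 * log(det(p$G)) -
      0.5 * (Ginv[1, 1] * U1^2 + 2 * Ginv[1, 2] * U1 * U2 + Ginv[2, 2] * U2^2)
    cc <- p$gamma * (p$fixed[[2]] + U2)
    haz <- function(u) p$lam * p$nu * u^(p$nu - 1) *
      exp(eta + p$gamma * U1 + cc * u)
    ch <- stats::integrate(haz, 0, Tt, rel.tol = 1e-10)$value
    lh <- log(p$lam * p$nu) + (p$nu - 1) * log(Tt) + eta + p$gamma * U1 + cc * Tt
    vals[i, j] <- exp(ll_long + ll_prior + delta * lh - ch)
  }
  w1 <- rep(diff(u1)[1], grid_n); w1[c(1, grid_n)] <- w1[1] / 2
  w2 <- rep(diff(u2)[1], grid_n); w2[c(1, grid_n)] <- w2[1] / 2
  log(drop(w1 %*% vals %*% w2))
}

# Dense marginal Gaussian log-likelihood of the random-slope LMM, built
# directly from V_i = Z G Z' + sigma2 I per subject.
oracle_lmm_loglik <- function(panel, fixed, G, sigma2) {
  df <- as.data.frame(panel)
  ll <- 0
  for (d in split(df, df$id)) {
    Z <- cbind(1, d$time)
    V <- Z %*% G %*% t(Z) + sigma2 * diag(nrow(d))
    mu <- fixed[[1]] + fixed[[2]] * d$time + fixed[[3]] * d$age[1]
    r <- d$y - mu
    ll <- ll - 0.5 * (nrow(d) * log(2 * pi) + determinant(V)$modulus[1] +
                        drop(t(r) %*% solve(V, r)))
  }
  ll
}

# Small deterministic dataset used by several structural tests.
make_tiny_dataset <- function(n = 8, seed = 42, gamma = 0.5, sigma2 = 0.1161) {
  p <- gen_params(n = n, gamma = gamma, lam = 2e-5, sigma2 = sigma2)
  generate_dataset(p, seed = seed)
}
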