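# Internal numerical helpers shared across modules.

# 15-point Kronrod rule on [-1, 1] (the K15 half of the classic (G7, K15) pair).
# Abscissae are symmetric; only the non-negative half is tabulated.
.k15_x <- c(0.991455371120813, 0.949107912342759, 0.864864423359769,
            0.741531185599394, 0.586087235467691, 0.405845151377397,
            0.207784955007898, 0.000000000000000)
.k15_w <- c(0.022935322010529, 0.063092092629979, 0.104790010322250,
            0.140653259715525, 0.169004726639267, 0.190350578064785,
            0.204432940075298, 0.209482141084728)

#' @noRd
gk15_nodes <- function() {
  x <- c(-.k15_x[1:7], rev(.k15_x[8:1]))
  w <- c(.k15_w[1:7], rev(.k15_w[8:1]))
  o <- order(x)
  list(x = x[o], w = w[o])
}

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows
#' @noRd
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# Truncated-normal draws by rejection; vectorized, deterministic under the
# current RNG state.
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

# MVN draws via a symmetric square root so that a singular (or zero) covariance
# degenerates gracefully to its point mass.
#' @noRd
rmvnorm2 <- function(n, mu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  rt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  z <- matrix(stats::rnorm(2L * n), nrow = n)
  sweep(z %*% rt, 2L, mu, "+")
}

# Tensor-product Gauss-Hermite grid for 2-D adaptive quadrature.
# Returns node pairs (z1, z2) and log weights including the exp(z^2) correction
# so that integral f(u) du = sum exp(lw) * 2*det(L) * f(m + sqrt(2) L z).
#' @noRd
gh2_grid <- function(k) {
  gh <- pracma::gaussHermite(k)
  z1 <- rep(gh$x, times = k)
  z2 <- rep(gh$x, each = k)
  lw <- rep(log(gh$w), times = k) + rep(log(gh$w), each = k) + z1^2 + z2^2
  list(z1 = z1, z2 = z2, lw = lw)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
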