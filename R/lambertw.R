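#' Principal branch of the Lambert W function
#'
#' Solves \eqn{w e^w = x} for \eqn{w \ge -1} (the principal branch
#' \eqn{W_0}), the inverse map needed to solve cumulative-hazard equations of
#' the form \eqn{c\,t\,e^{k t} = h}. Vectorized; Halley iteration from a
#' branch-aware starting point, converging to ~1e-15 relative error.
#'
#' @param x numeric vector, each element >= -1/e.
#' @return numeric vector `w` with `w * exp(w) == x`.
#' @examples
#' lambert_w0(exp(1))        # 1
#' lambert_w0(1)             # 0.567143...
#' @export
lambert_w0 <- function(x) {
  if (any(x < -exp(-1) - 1e-12, na.rm = TRUE))
    stop("lambert_w0: argument below -1/e is outside the principal branch")
  x <- pmax(x, -exp(-1))
  w <- numeric(length(x))
  # starting points: series near the branch point, log asymptote for large x
  near <- x < -0.25
  if (any(near)) {
    p <- sqrt(2 * (exp(1) * x[near] + 1))
    w[near] <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  mid <- !near & x < 3
  w[mid] <- x[mid] * exp(-0.4 * pmax(x[mid], 0))  # crude but in basin
  big <- x >= 3
  if (any(big)) {
    lx <- log(x[big])
    w[big] <- lx - log(lx)
  }
  for (iter in 1:50) {
    ew <- exp(w)
    f <- w * ew - x
    # Halley step
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- f / denom
    step[!is.finite(step)] <- 0
    w <- w - step
    if (all(abs(step) <= 1e-14 * pmax(1, abs(w)))) break
  }
  # exact endpoints
  w[x == -exp(-1)] <- -1
  w[x == 0] <- 0
  w
}
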