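# Independent oracles: straightforward arithmetic implementations used to
# check the package's vectorised / incremental code paths.  These stay
# deliberately naive (explicit loops, ratio-scale products).

# Closed-form 3PL probability.
oracle_p3pl <- function(a, b, c, theta, scaling = 1.7) {
  c + (1 - c) / (1 + exp(-scaling * a * (theta - b)))
}

# Brute-force likelihood-ratio product on the ratio scale: responses u on
# items (a, b, c), numerator evaluated at theta_num[i], denominator at
# theta_den[i].
oracle_lr <- function(a, b, c, u, theta_num, theta_den, scaling = 1.7) {
  num <- den <- 1
  for (i in seq_along(u)) {
    pn <- oracle_p3pl(a[i], b[i], c[i], theta_num[i], scaling)
    pd <- oracle_p3pl(a[i], b[i], c[i], theta_den[i], scaling)
    num <- num * pn^u[i] * (1 - pn)^(1 - u[i])
    den <- den * pd^u[i] * (1 - pd)^(1 - u[i])
  }
  num / den
}

# Grid-search maximiser of the Bernoulli log-likelihood (step 1e-3).
oracle_mle_grid <- function(a, b, c, u, scaling = 1.7,
                            bounds = c(-4, 4), step = 1e-3) {
  th <- seq(bounds[1], bounds[2], by = step)
  ll <- numeric(length(th))
  for (i in seq_along(u)) {
    p <- oracle_p3pl(a[i], b[i], c[i], th, scaling)
    ll <- ll + u[i] * log(p) + (1 - u[i]) * log(1 - p)
  }
  th[which.max(ll)]
}

# Fisher information by finite-difference curvature of the expected
# log-likelihood f(t) = P(theta) log P(t) + Q(theta) log Q(t) at t = theta.
oracle_fisher_curvature <- function(a, b, c, theta, scaling = 1.7,
                                    h = 1e-4) {
  f <- function(t) {
    p0 <- oracle_p3pl(a, b, c, theta, scaling)
    pt <- oracle_p3pl(a, b, c, t, scaling)
    p0 * log(pt) + (1 - p0) * log(1 - pt)
  }
  -(f(theta + h) - 2 * f(theta) + f(theta - h)) / h^2
}

# Direct 2x2 determinant.
oracle_det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
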