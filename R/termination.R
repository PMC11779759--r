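# Termination statistics: Wald thresholds, SPRT-SF and SPRT-C likelihood
# ratios, conditional-normal imputation, the P-SPRT pre-rule, and the
# interim / forced decision logic.  All likelihood ratios are computed in
# log space internally to avoid under/overflow on long products.

#' Indifference region bounds
#'
#' The SPRT tests trait-at-upper-bound against trait-at-lower-bound of an
#' indifference region of half-width `delta` around the cutoff.
#'
#' @param cutoff Cutoff point on the trait scale.
#' @param delta Half-width of the indifference region (>= 0).
#' @return Named numeric `c(theta_L, theta_U) = cutoff -/+ delta`.
#' @export
indifference_bounds <- function(cutoff, delta) {
  if (!is.finite(delta) || delta < 0) {
    stop("`delta` must be nonnegative", call. = FALSE)
  }
  c(theta_L = cutoff - delta, theta_U = cutoff + delta)
}

#' Wald decision thresholds
#'
#' `A = (1 - beta) / alpha` and `B = beta / (1 - alpha)` for nominal type I
#' and type II error rates.
#'
#' @param alpha,beta Error rates in `(0, 0.5)`.
#' @return Named numeric `c(A, B)` with `A > 1 > B > 0`.
#' @export
wald_thresholds <- function(alpha, beta) {
  for (r in list(alpha, beta)) {
    if (!is.finite(r) || r <= 0 || r >= 0.5) {
      stop("`alpha` and `beta` must lie in (0, 0.5)", call. = FALSE)
    }
  }
  c(A = (1 - beta) / alpha, B = beta / (1 - alpha))
}

#' Classification specification
#'
#' Bundles cutoffs, the indifference half-width and the nominal error rates,
#' together with the derived per-dimension bounds `theta_L`/`theta_U` and
#' Wald thresholds `A`/`B`.
#'
#' @param cutoffs Numeric vector of per-dimension cutoff points.
#' @param delta Indifference half-width (> 0 in applications; 0 allowed as a
#'   degenerate region).
#' @param alpha,beta Nominal error rates in `(0, 0.5)`.
#' @return An object of class `classification_spec`.
#' @export
classification_spec <- function(cutoffs, delta = 0.2,
                                alpha = 0.05, beta = 0.05) {
  thr <- wald_thresholds(alpha, beta)
  bounds <- vapply(cutoffs, indifference_bounds, numeric(2L), delta = delta)
  structure(list(
    cutoffs = as.numeric(cutoffs), delta = delta,
    alpha = alpha, beta = beta,
    theta_L = bounds["theta_L", ], theta_U = bounds["theta_U", ],
    A = thr[["A"]], B = thr[["B"]],
    log_A = log(thr[["A"]]), log_B = log(thr[["B"]])
  ), class = "classification_spec")
}

#' @export
print.classification_spec <- function(x, ...) {
  cat("<classification_spec> cutoffs (", paste(x$cutoffs, collapse = ", "),
      "), delta ", x$delta, ", alpha ", x$alpha, ", beta ", x$beta,
      "; A = ", format(x$A), ", B = ", format(x$B), "\n", sep = "")
  invisible(x)
}

#' Population trait model
#'
#' Multivariate normal latent-trait population with known mean vector and
#' covariance.  The default is the standardised model used throughout the
#' simulations: zero means, unit variances, common correlation `rho`.
#'
#' @param rho Between-dimension correlation, `|rho| < 1`.
#' @param D Number of dimensions.
#' @param mu Mean vector.
#' @param sd Vector of marginal standard deviations.
#' @return An object of class `population_model` with fields `mu`, `sigma`
#'   (covariance matrix) and `rho`.
#' @export
population_model <- function(rho, D = 2L, mu = rep(0, D), sd = rep(1, D)) {
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  }
  R <- matrix(rho, D, D)
  diag(R) <- 1
  sigma <- diag(sd, D) %*% R %*% diag(sd, D)
  structure(list(mu = as.numeric(mu), sigma = sigma, rho = rho),
            class = "population_model")
}

#' Conditional-normal parameters of a non-target trait
#'
#' Mean and variance of the query dimension's trait given the known
#' dimension's trait equals `a`, under the bivariate-normal population
#' model: `mean = mu_q + (sigma_q / sigma_k) * rho * (a - mu_k)` and
#' `var = (1 - rho^2) * sigma_q^2`.  With standard-normal margins this is
#' `rho * a` and `1 - rho^2`.
#'
#' @param pop A [population_model()].
#' @param known_d Dimension being conditioned on.
#' @param a Conditioning trait value.
#' @param query_d Dimension whose conditional distribution is wanted.
#' @return Named list with `mean` and `var`.
#' @export
conditional_params <- function(pop, known_d, a, query_d) {
  if (known_d == query_d) stop("`known_d` must differ from `query_d`",
                               call. = FALSE)
  if (abs(pop$rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  s_k <- sqrt(pop$sigma[known_d, known_d])
  s_q <- sqrt(pop$sigma[query_d, query_d])
  rho_qk <- pop$sigma[query_d, known_d] / (s_q * s_k)
  list(mean = pop$mu[[query_d]] + (s_q / s_k) * rho_qk * (a - pop$mu[[known_d]]),
       var = (1 - rho_qk^2) * s_q^2)
}

# Bernoulli log-likelihood of responses u at probabilities p.
bernoulli_ll <- function(u, p) sum(u * log(p) + (1 - u) * log1p(-p))

# Match responses (item_id, u) to bank rows; returns list(idx, u).
match_responses <- function(responses, bank) {
  idx <- match(responses$item_id, bank$item_id)
  if (anyNA(idx)) {
    stop("unknown item_id in responses: ",
         paste(responses$item_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  list(idx = idx, u = as.integer(responses$u))
}

#' SPRT-SF likelihood ratio
#'
#' Per-dimension SPRT likelihood ratio using only the items that load on the
#' target dimension: the Bernoulli likelihood of their responses at the
#' upper indifference bound divided by the likelihood at the lower bound.
#' Items on other dimensions cancel and have no effect.
#'
#' @param target_d Target dimension.
#' @param responses Data frame with columns `item_id`, `u`.
#' @param bank An [item_bank()].
#' @param spec A [classification_spec()].
#' @param log If `TRUE`, return the log likelihood ratio.
#' @inheritParams prob_3pl
#' @return Likelihood ratio (or its log).
#' @export
lr_sf <- function(target_d, responses, bank, spec, log = FALSE,
                  scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  m <- match_responses(responses, bank)
  sel <- bank$dimension[m$idx] == target_d
  i <- m$idx[sel]
  llr <- bernoulli_ll(m$u[sel],
                      p3pl(bank$a[i], bank$b[i], bank$c[i],
                           spec$theta_U[[target_d]], scaling)) -
         bernoulli_ll(m$u[sel],
                      p3pl(bank$a[i], bank$b[i], bank$c[i],
                           spec$theta_L[[target_d]], scaling))
  if (log) llr else exp(llr)
}

#' SPRT-C likelihood ratio
#'
#' SPRT likelihood ratio over all administered items.  Target-dimension
#' items are evaluated at the upper (numerator) and lower (denominator)
#' indifference bounds; non-target items are evaluated at the conditional
#' expected value of their trait given the target trait equals that bound
#' (see [conditional_params()]).  With `rho = 0` the non-target factors
#' cancel and the statistic reduces to [lr_sf()].
#'
#' @inheritParams lr_sf
#' @param pop A [population_model()].
#' @return Likelihood ratio (or its log).
#' @export
lr_c <- function(target_d, responses, bank, spec, pop, log = FALSE,
                 scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  m <- match_responses(responses, bank)
  dims <- bank$dimension[m$idx]
  eval_at <- function(bound) {
    th <- numeric(length(dims))
    th[dims == target_d] <- bound
    for (d in setdiff(unique(dims), target_d)) {
      th[dims == d] <- conditional_params(pop, target_d, bound, d)$mean
    }
    th
  }
  i <- m$idx
  llr <- bernoulli_ll(m$u, p3pl(bank$a[i], bank$b[i], bank$c[i],
                                eval_at(spec$theta_U[[target_d]]), scaling)) -
         bernoulli_ll(m$u, p3pl(bank$a[i], bank$b[i], bank$c[i],
                                eval_at(spec$theta_L[[target_d]]), scaling))
  if (log) llr else exp(llr)
}

#' P-SPRT pre-rule statistic
#'
#' `phi = rho * (theta_hat_1 - cutoff_1) * (theta_hat_2 - cutoff_2)`: the
#' correlation-weighted product of the provisional trait deviations from the
#' cutoffs.  A positive value means the provisional position of the examinee
#' is concordant with the correlation, so conditional imputation (SPRT-C)
#' helps; otherwise it misleads and the plain SPRT-SF is preferred.
#'
#' @param rho Between-dimension correlation.
#' @param theta_hat Length-2 provisional trait estimate.
#' @param cutoffs Length-2 cutoff vector.
#' @return The scalar pre-rule product.
#' @export
phi <- function(rho, theta_hat, cutoffs) {
  if (length(theta_hat) != 2L || length(cutoffs) != 2L) {
    stop("the pre-rule is defined for two dimensions", call. = FALSE)
  }
  rho * (theta_hat[[1L]] - cutoffs[[1L]]) * (theta_hat[[2L]] - cutoffs[[2L]])
}

#' Choose the termination criterion from the pre-rule
#'
#' @param phi_value Value of [phi()].
#' @return `"C"` (SPRT-C) if `phi_value > 0`, else `"SF"` (SPRT-SF).
#' @export
choose_criterion <- function(phi_value) {
  if (phi_value > 0) "C" else "SF"
}

# log-space decision kernel shared by decide() and the engine.
decide_log <- function(llr, log_A, log_B) {
  if (llr >= log_A) "above" else if (llr < log_B) "below" else "continue"
}

forced_decide_log <- function(llr, log_A, log_B) {
  # classify toward the boundary the log-LR is strictly closer to;
  # exact tie retains the null hypothesis (below)
  if (abs(llr - log_A) < abs(llr - log_B)) "above" else "below"
}

#' Interim SPRT decision
#'
#' Classify above the cutoff when `lr >= A` (reject H0), below when
#' `lr < B` (retain H0), otherwise continue testing.
#'
#' @param lr Likelihood ratio (> 0), on the ratio scale.
#' @param spec A [classification_spec()].
#' @return One of `"above"`, `"below"`, `"continue"`.
#' @export
decide <- function(lr, spec) {
  if (!is.finite(lr) && !identical(lr, Inf)) stop("`lr` must be positive",
                                                  call. = FALSE)
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  decide_log(log(lr), spec$log_A, spec$log_B)
}

#' Forced classification at maximum test length
#'
#' When the maximum test length is reached without an interim decision, the
#' classification is forced toward the threshold whose log value the log
#' likelihood ratio is closer to: above (reject H0) when
#' `|log lr - log A| < |log lr - log B|`, below otherwise; an exact tie
#' retains H0 (below).
#'
#' @inheritParams decide
#' @return `"above"` or `"below"`.
#' @export
forced_decide <- function(lr, spec) {
  if (lr <= 0 || is.na(lr)) stop("`lr` must be positive", call. = FALSE)
  forced_decide_log(log(lr), spec$log_A, spec$log_B)
}
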