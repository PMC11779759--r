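# Item response model for the between-item multidimensional 3PL:
# every item loads on exactly one dimension, so all item-level quantities
# reduce to unidimensional 3PL expressions in the loaded trait component.

# Default logistic scaling constant.  1.7 makes the logistic approximate
# the normal-ogive metric and is what reproduces the reference simulation
# results; pass scaling = 1 for the unscaled logistic.
DEFAULT_SCALING <- 1.7

# Vectorised 3PL response probability (internal workhorse).
# a, b, c, theta recycle under the usual rules.
p3pl <- function(a, b, c, theta, scaling = DEFAULT_SCALING) {
  c + (1 - c) * stats::plogis(scaling * a * (theta - b))
}

#' Three-parameter logistic response probability
#'
#' Probability of a correct response under the 3PL model,
#' \eqn{P = c + (1-c) / (1 + \exp(-Da(\theta - b)))}, evaluated at the trait
#' component the item loads on, with logistic scaling constant `D = scaling`.
#'
#' @param item An item: a list or one-row data frame with fields `a`
#'   (discrimination, > 0), `b` (difficulty), `c` (guessing, in `[0, 1)`)
#'   and `dimension` (loaded dimension, 1-based).
#' @param theta Numeric trait vector.  If longer than 1, the component
#'   `theta[item$dimension]` is used; a scalar is taken as the value on the
#'   loaded dimension.
#' @param scaling Logistic scaling constant (default 1.7; use 1 for the
#'   unscaled logistic).
#' @return Response probability in `(c, 1)`.
#' @examples
#' it <- list(a = 1, b = 0, c = 0.2, dimension = 1)
#' prob_3pl(it, 0)      # 0.6
#' prob_3pl(it, c(0, 5))  # unchanged: item loads on dimension 1
#' @seealso [fisher_info()], [prob_rasch()]
#' @export
prob_3pl <- function(item, theta, scaling = DEFAULT_SCALING) {
  item <- validate_item(item)
  if (!all(is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  th <- if (length(theta) > 1L) theta[[item$dimension]] else theta[[1L]]
  p3pl(item$a, item$b, item$c, th, scaling)
}

#' Rasch model response probability
#'
#' `P = logistic(theta - b)`; identical to [prob_3pl()] with
#' `a = 1, c = 0, scaling = 1`.
#'
#' @param b Item difficulty (logit scale).
#' @param theta Scalar latent trait.
#' @return Response probability in `(0, 1)`.
#' @export
prob_rasch <- function(b, theta) {
  if (!all(is.finite(b)) || !all(is.finite(theta))) {
    stop("`b` and `theta` must be finite", call. = FALSE)
  }
  stats::plogis(theta - b)
}

# Vectorised scalar Fisher information of a 3PL item at trait value theta
# (on the loaded dimension): (Da)^2 * (Q/P) * ((P - c)/(1 - c))^2.
info3pl <- function(a, b, c, theta, scaling = DEFAULT_SCALING) {
  p <- p3pl(a, b, c, theta, scaling)
  (scaling * a)^2 * ((1 - p) / p) * ((p - c) / (1 - c))^2
}

#' Fisher information of an item
#'
#' Scalar Fisher information of a 3PL item on its loaded dimension,
#' \eqn{I(\theta) = (Da)^2 (Q/P) ((P - c)/(1 - c))^2} with scaling constant
#' `D = scaling`.  Under the between-item
#' structure the full D-by-D item information matrix is this scalar at the
#' (dimension, dimension) diagonal entry and zero elsewhere; see
#' [info_matrix()].
#'
#' @inheritParams prob_3pl
#' @return Nonnegative information scalar.
#' @export
fisher_info <- function(item, theta, scaling = DEFAULT_SCALING) {
  item <- validate_item(item)
  th <- if (length(theta) > 1L) theta[[item$dimension]] else theta[[1L]]
  info3pl(item$a, item$b, item$c, th, scaling)
}

#' Item information matrix under the between-item structure
#'
#' @inheritParams prob_3pl
#' @param D Number of dimensions.
#' @return A `D`-by-`D` matrix, zero except for the loaded-dimension
#'   diagonal entry, which holds [fisher_info()].
#' @export
info_matrix <- function(item, theta, D, scaling = DEFAULT_SCALING) {
  item <- validate_item(item)
  M <- matrix(0, D, D)
  M[item$dimension, item$dimension] <- fisher_info(item, theta, scaling)
  M
}

#' Simulate a dichotomous item response
#'
#' Compares the 3PL probability with a uniform draw: the response is correct
#' (1) iff `uniform_draw < prob_3pl(item, theta_true)`.
#'
#' @inheritParams prob_3pl
#' @param theta_true True trait vector of the examinee.
#' @param uniform_draw A number in `[0, 1)`.
#' @return Integer 0 or 1.
#' @export
simulate_response <- function(item, theta_true, uniform_draw,
                              scaling = DEFAULT_SCALING) {
  if (!is.numeric(uniform_draw) || is.na(uniform_draw) ||
      uniform_draw < 0 || uniform_draw >= 1) {
    stop("`uniform_draw` must lie in [0, 1)", call. = FALSE)
  }
  as.integer(uniform_draw < prob_3pl(item, theta_true, scaling))
}

# 1-D bounded MLE for one dimension's Bernoulli log-likelihood.
# Perfect / zero response patterns clamp to the interval bounds (the
# likelihood is then monotone in theta).  Guessing can make the likelihood
# multimodal for short mixed patterns, so a coarse grid scan brackets the
# global maximum before local refinement.
mle_1d <- function(a, b, c, u, bounds = c(-4, 4), tol = 1e-6,
                   scaling = DEFAULT_SCALING) {
  if (length(u) == 0L) return(0)
  if (all(u == 1L)) return(bounds[[2L]])
  if (all(u == 0L)) return(bounds[[1L]])
  negll <- function(th) {
    p <- p3pl(a, b, c, th, scaling)
    -sum(u * log(p) + (1 - u) * log1p(-p))
  }
  grid <- seq(bounds[[1L]], bounds[[2L]], length.out = 33L)
  best <- which.min(vapply(grid, negll, numeric(1L)))
  lo <- grid[[max(1L, best - 1L)]]
  hi <- grid[[min(length(grid), best + 1L)]]
  th <- stats::optimize(negll, c(lo, hi), tol = tol)$minimum
  # the bracket endpoints can beat the interior optimum when the maximum
  # sits at a bound
  cand <- c(th, lo, hi)
  th <- cand[[which.min(c(negll(th), negll(lo), negll(hi)))]]
  min(max(th, bounds[[1L]]), bounds[[2L]])
}

#' Maximum-likelihood trait estimation
#'
#' Per-dimension MLE of the latent trait vector.  Because the model is
#' between-item, the likelihood factorises over dimensions and each
#' component is a one-dimensional bounded maximisation of the Bernoulli
#' log-likelihood over the items loading on that dimension.  Dimensions with
#' no administered items return the population mean, 0.
#'
#' @param responses Data frame with columns `item_id` and `u` (0/1).
#' @param bank An [item_bank()].
#' @param bounds Length-2 trait interval; estimates are clamped to it.
#' @param tol Optimisation tolerance.
#' @inheritParams prob_3pl
#' @return Numeric trait vector of length `D(bank)`.
#' @export
mle_estimate <- function(responses, bank, bounds = c(-4, 4), tol = 1e-6,
                         scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  D <- attr(bank, "D")
  idx <- match(responses$item_id, bank$item_id)
  if (anyNA(idx)) {
    stop("unknown item_id in responses: ",
         paste(responses$item_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  u <- as.integer(responses$u)
  theta <- numeric(D)
  for (d in seq_len(D)) {
    sel <- bank$dimension[idx] == d
    theta[[d]] <- mle_1d(bank$a[idx][sel], bank$b[idx][sel],
                         bank$c[idx][sel], u[sel], bounds = bounds,
                         tol = tol, scaling = scaling)
  }
  theta
}

# Shared item validator: accepts a list or one-row data frame.
validate_item <- function(item) {
  for (f in c("a", "b", "c", "dimension")) {
    if (is.null(item[[f]])) stop("item lacks field `", f, "`", call. = FALSE)
  }
  if (!is.finite(item$a) || item$a <= 0) {
    stop("item discrimination `a` must be > 0", call. = FALSE)
  }
  if (!is.finite(item$c) || item$c < 0 || item$c >= 1) {
    stop("item guessing `c` must lie in [0, 1)", call. = FALSE)
  }
  item
}
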