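# Simulation study runner: synthetic bank / examinee generation, full
# condition runs with aggregate metrics (PCC, ATL, PCC per item, LOSS,
# forced-at-maximum percentage) and operating-characteristic curves.

# Derive a reproducible triple of sub-seeds (bank / examinees / responses)
# from one base seed, without disturbing the caller's RNG state.
derive_seeds <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  list(bank = s[[1L]], examinees = s[[2L]], responses = s[[3L]])
}

#' Generate examinee trait vectors
#'
#' Draws `n` trait vectors from a multivariate standard-normal population
#' with common correlation `rho` (unit-variance margins).  Uses the current
#' RNG state.
#'
#' @param n Number of examinees.
#' @param rho Between-dimension correlation, `|rho| < 1`.
#' @param D Number of dimensions.
#' @return An `n`-by-`D` numeric matrix.
#' @export
generate_examinees <- function(n, rho, D = 2L) {
  pop <- population_model(rho, D)
  z <- matrix(stats::rnorm(n * D), n, D)
  z %*% chol(pop$sigma)
}

#' True classification of a trait vector
#'
#' Ground truth for accuracy metrics: above iff the true trait strictly
#' exceeds the cutoff on that dimension (ties classify below).
#'
#' @param theta_true Trait vector.
#' @param cutoffs Cutoff vector.
#' @return Character vector of `"above"`/`"below"` per dimension.
#' @export
true_classification <- function(theta_true, cutoffs) {
  ifelse(theta_true > cutoffs, "above", "below")
}

#' Define a simulation condition
#'
#' One cell of the simulation design: correlation, cutoff pair, indifference
#' half-width, error rates, number of examinees, bank size, termination
#' criterion, length limits and the seed from which the bank / examinee /
#' response sub-seeds are derived.
#'
#' @param rho Between-dimension correlation.
#' @param cutoffs Cutoff vector (length `D`).
#' @param criterion `"P"`, `"SF"` or `"C"`.
#' @param delta,alpha,beta Classification-spec parameters (defaults 0.2,
#'   0.05, 0.05).
#' @param n_examinees Examinees per condition (default 5000).
#' @param items_per_dim Bank size per dimension (default 300).
#' @param min_items,max_items Per-dimension length limits (defaults 3, 30).
#' @param seed Base seed; expanded into a bank/examinees/responses triple.
#' @param seeds Optional explicit seed triple (named list), overriding
#'   `seed`.
#' @inheritParams prob_3pl
#' @return An object of class `simulation_condition`.
#' @export
simulation_condition <- function(rho, cutoffs, criterion = c("P", "SF", "C"),
                                 delta = 0.2, alpha = 0.05, beta = 0.05,
                                 n_examinees = 5000L, items_per_dim = 300L,
                                 min_items = 3L, max_items = 30L,
                                 seed = 1L, seeds = NULL,
                                 scaling = DEFAULT_SCALING) {
  criterion <- match.arg(criterion)
  if (n_examinees < 1L) stop("`n_examinees` must be >= 1", call. = FALSE)
  if (is.null(seeds)) seeds <- derive_seeds(seed)
  structure(list(rho = rho, cutoffs = as.numeric(cutoffs),
                 criterion = criterion, delta = delta,
                 alpha = alpha, beta = beta,
                 n_examinees = as.integer(n_examinees),
                 items_per_dim = as.integer(items_per_dim),
                 min_items = as.integer(min_items),
                 max_items = as.integer(max_items),
                 seeds = seeds, scaling = scaling),
            class = "simulation_condition")
}

# Aggregate per-examinee records into the condition-level metrics.
# Per-examinee LOSS is 100 * wrong + L; its mean equals
# 100 * (1 - PCC/100) + ATL exactly, and PCC per item is the ratio of the
# two aggregates (not a mean of per-examinee ratios).
condition_metrics <- function(correct_both, total_length, forced_both) {
  pcc <- 100 * mean(correct_both)
  atl <- mean(total_length)
  data.frame(
    pcc = pcc, atl = atl, pcc_per_item = pcc / atl,
    loss = mean(100 * (1 - correct_both) + total_length),
    pct_forced_both = 100 * mean(forced_both),
    n = length(total_length)
  )
}

#' Run one simulation condition
#'
#' Generates (or reuses) a bank and an examinee sample, administers the full
#' test to every examinee under the condition's termination criterion, and
#' aggregates the accuracy and efficiency metrics.  An examinee counts as a
#' correct classification only when both dimensions are classified
#' correctly; ATL is the mean total (both-dimension) test length.
#'
#' @param cond A [simulation_condition()].
#' @param bank Optional [item_bank()]; when `NULL`, generated from the
#'   condition's bank seed (so all criteria run on the same bank when the
#'   same seed triple is used).
#' @param examinees Optional trait matrix; when `NULL`, generated from the
#'   examinee seed.
#' @param keep_examinees If `TRUE`, attach the per-examinee records as
#'   attribute `"examinees"`.
#' @return A one-row data frame of class `condition_result` with columns
#'   `rho`, `cutoff1`, `cutoff2`, `criterion`, `pcc`, `atl`,
#'   `pcc_per_item`, `loss`, `pct_forced_both`, `n`.
#' @export
run_condition <- function(cond, bank = NULL, examinees = NULL,
                          keep_examinees = FALSE) {
  D <- length(cond$cutoffs)
  if (is.null(bank)) {
    set.seed(cond$seeds$bank)
    bank <- generate_bank(cond$items_per_dim, D = D)
  }
  if (is.null(examinees)) {
    set.seed(cond$seeds$examinees)
    examinees <- generate_examinees(cond$n_examinees, cond$rho, D = D)
  }
  spec <- classification_spec(cond$cutoffs, cond$delta, cond$alpha, cond$beta)
  pop <- population_model(cond$rho, D = D)
  tables <- condition_tables(bank, spec, pop, scaling = cond$scaling)
  n <- nrow(examinees)
  correct_both <- logical(n)
  total_length <- integer(n)
  forced_both <- logical(n)
  per_dim_correct <- matrix(NA, n, D)
  set.seed(cond$seeds$responses)
  for (i in seq_len(n)) {
    res <- administer_examinee(examinees[i, ], criterion = cond$criterion,
                               min_items = cond$min_items,
                               max_items = cond$max_items, tables = tables)
    correct_both[[i]] <- all(res$correct)
    total_length[[i]] <- res$total_length
    forced_both[[i]] <- all(res$forced)
    per_dim_correct[i, ] <- res$correct
  }
  out <- cbind(
    data.frame(rho = cond$rho, cutoff1 = cond$cutoffs[[1L]],
               cutoff2 = if (D >= 2L) cond$cutoffs[[2L]] else NA_real_,
               criterion = cond$criterion),
    condition_metrics(correct_both, total_length, forced_both)
  )
  class(out) <- c("condition_result", "data.frame")
  attr(out, "seeds") <- cond$seeds
  if (keep_examinees) {
    attr(out, "examinees") <- data.frame(
      theta = examinees, correct_both = correct_both,
      total_length = total_length, forced_both = forced_both
    )
  }
  out
}

#' Run a grid of simulation conditions
#'
#' Crosses correlations, cutoff pairs and termination criteria.  Within one
#' (rho, cutoffs) cell, all criteria share the same seed triple, hence the
#' same bank, examinees and response uniforms, so criteria are compared on
#' identical data (and are bit-identical when `rho = 0`).
#'
#' @param rhos Vector of correlations.
#' @param cutoff_sets List of cutoff vectors.
#' @param criteria Character vector among `"SF"`, `"C"`, `"P"`.
#' @param n_examinees,items_per_dim,delta,alpha,beta,min_items,max_items
#'   Passed to [simulation_condition()].
#' @param seed Base seed; each cell uses a sub-seed derived from it.
#' @return A data frame with one row per (rho, cutoffs, criterion).
#' @export
run_study <- function(rhos, cutoff_sets, criteria = c("SF", "C", "P"),
                      n_examinees = 5000L, items_per_dim = 300L,
                      delta = 0.2, alpha = 0.05, beta = 0.05,
                      min_items = 3L, max_items = 30L, seed = 1L,
                      scaling = DEFAULT_SCALING) {
  if (!is.list(cutoff_sets)) cutoff_sets <- list(cutoff_sets)
  cells <- expand.grid(rho_i = seq_along(rhos),
                       cut_i = seq_along(cutoff_sets))
  rows <- list()
  for (j in seq_len(nrow(cells))) {
    rho <- rhos[[cells$rho_i[[j]]]]
    cutoffs <- cutoff_sets[[cells$cut_i[[j]]]]
    cell_seed <- as.integer((as.numeric(seed) * 1009 + j) %%
                              (.Machine$integer.max - 2)) + 1L
    seeds <- derive_seeds(cell_seed)
    set.seed(seeds$bank)
    bank <- generate_bank(items_per_dim, D = length(cutoffs))
    for (crit in criteria) {
      cond <- simulation_condition(rho, cutoffs, criterion = crit,
                                   delta = delta, alpha = alpha, beta = beta,
                                   n_examinees = n_examinees,
                                   items_per_dim = items_per_dim,
                                   min_items = min_items,
                                   max_items = max_items, seeds = seeds,
                                   scaling = scaling)
      rows[[length(rows) + 1L]] <- run_condition(cond, bank = bank)
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Operating-characteristic / average-test-length curve
#'
#' For each ability on a dimension-1 grid (dimension-2 ability fixed), runs
#' repeated administrations and records the percentage of replications
#' accepting H0 on dimension 1 (classified below the cutoff) and the
#' dimension-1 test length as a percentage of its maximum.
#'
#' @param abilities Dimension-1 ability grid.
#' @param fixed_ability Fixed dimension-2 ability (default 1.0).
#' @param reps Replications per grid point (default 100).
#' @param rho,cutoffs,criterion,delta,alpha,beta,items_per_dim,min_items,max_items
#'   Condition parameters, as in [simulation_condition()].
#' @param bank Optional bank; generated from the seed when `NULL`.
#' @param seed Base seed.
#' @inheritParams prob_3pl
#' @return Data frame with columns `ability`, `oc` (percent accepting H0 on
#'   dimension 1), `atl_dim1` (mean items), `atl_pct_dim1` (percent of
#'   `max_items`), `reps`.
#' @export
oc_atl_curve <- function(abilities, fixed_ability = 1.0, reps = 100L,
                         rho = 0.5, cutoffs = c(0, 0),
                         criterion = c("P", "SF", "C"),
                         delta = 0.2, alpha = 0.05, beta = 0.05,
                         items_per_dim = 300L, min_items = 3L,
                         max_items = 30L, bank = NULL, seed = 1L,
                         scaling = DEFAULT_SCALING) {
  criterion <- match.arg(criterion)
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  seeds <- derive_seeds(seed)
  if (is.null(bank)) {
    set.seed(seeds$bank)
    bank <- generate_bank(items_per_dim, D = 2L)
  }
  spec <- classification_spec(cutoffs, delta, alpha, beta)
  pop <- population_model(rho, D = 2L)
  tables <- condition_tables(bank, spec, pop, scaling = scaling)
  set.seed(seeds$responses)
  out <- lapply(abilities, function(ab) {
    below <- logical(reps)
    k1 <- integer(reps)
    for (r in seq_len(reps)) {
      res <- administer_examinee(c(ab, fixed_ability), criterion = criterion,
                                 min_items = min_items,
                                 max_items = max_items, tables = tables)
      below[[r]] <- res$classification[[1L]] == "below"
      k1[[r]] <- res$lengths[[1L]]
    }
    data.frame(ability = ab, oc = 100 * mean(below), atl_dim1 = mean(k1),
               atl_pct_dim1 = 100 * mean(k1) / max_items, reps = reps)
  })
  do.call(rbind, out)
}

#' Generate study fixtures
#'
#' `"tiny"` produces a fast test fixture (20 items per dimension, 50
#' examinees); `"full"` produces the complete stated design (300 items per
#' dimension, 5000 examinees).  Identical seeds yield identical fixtures.
#'
#' @param size `"tiny"` or `"full"`.
#' @param rho Correlation of the examinee population (default 0.5).
#' @param seed Base seed (default 101).
#' @return List with `bank` (an [item_bank()]), `examinees` (trait matrix),
#'   `rho` and the derived `seeds`.
#' @export
fixture_generator <- function(size = c("tiny", "full"), rho = 0.5,
                              seed = 101L) {
  size <- match.arg(size)
  items_per_dim <- if (size == "tiny") 20L else 300L
  n <- if (size == "tiny") 50L else 5000L
  seeds <- derive_seeds(seed)
  set.seed(seeds$bank)
  bank <- generate_bank(items_per_dim, D = 2L)
  set.seed(seeds$examinees)
  examinees <- generate_examinees(n, rho, D = 2L)
  list(bank = bank, examinees = examinees, rho = rho, seeds = seeds)
}
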