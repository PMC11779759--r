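# Segall-style Bayesian item selection: pick the unadministered candidate
# maximising the determinant of the posterior information matrix, with all
# item information evaluated at the cutoff vector (cutoff-targeted
# selection, not estimate-targeted CAT selection).

#' Selection context
#'
#' Holds the accumulated information of administered items (evaluated at the
#' cutoff vector), the prior precision matrix (inverse population
#' covariance), and the eligible candidate pool.
#'
#' @param bank An [item_bank()].
#' @param cutoffs Cutoff vector (length `D`).
#' @param pop A [population_model()]; its covariance inverse is the prior
#'   precision.
#' @param administered Integer vector of administered item ids.
#' @param eligible Item ids eligible for selection; defaults to all
#'   unadministered items.
#' @inheritParams prob_3pl
#' @return An object of class `selection_context`.
#' @export
selection_context <- function(bank, cutoffs, pop,
                              administered = integer(0), eligible = NULL,
                              scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  D <- attr(bank, "D")
  acc <- matrix(0, D, D)
  if (length(administered)) {
    idx <- match(administered, bank$item_id)
    if (anyNA(idx)) stop("unknown administered item_id", call. = FALSE)
    info <- info3pl(bank$a[idx], bank$b[idx], bank$c[idx],
                    cutoffs[bank$dimension[idx]], scaling)
    for (d in seq_len(D)) {
      acc[d, d] <- sum(info[bank$dimension[idx] == d])
    }
  }
  if (is.null(eligible)) eligible <- setdiff(bank$item_id, administered)
  structure(list(prior_precision = solve(pop$sigma), acc = acc,
                 administered = as.integer(administered),
                 eligible = as.integer(eligible), D = D),
            class = "selection_context")
}

#' Posterior information determinant of a candidate item
#'
#' Determinant of prior precision + accumulated administered-item
#' information + the candidate's rank-1 information, all evaluated at the
#' cutoff vector.  Adding a positive-information candidate never decreases
#' the determinant.
#'
#' @param ctx A [selection_context()].
#' @param candidate An item (list or one-row data frame).
#' @param cutoffs Cutoff vector.
#' @inheritParams prob_3pl
#' @return The determinant.
#' @export
posterior_info_determinant <- function(ctx, candidate, cutoffs,
                                       scaling = DEFAULT_SCALING) {
  M <- ctx$prior_precision + ctx$acc
  d <- candidate$dimension
  M[d, d] <- M[d, d] + fisher_info(candidate, cutoffs[[d]], scaling)
  det(M)
}

#' Select the next item
#'
#' Argmax of [posterior_info_determinant()] over the eligible pool; exact
#' determinant ties are broken by the lowest `item_id`.
#'
#' @inheritParams posterior_info_determinant
#' @param bank An [item_bank()].
#' @return The selected `item_id`.
#' @export
select_next_item <- function(ctx, bank, cutoffs,
                             scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  idx <- match(ctx$eligible, bank$item_id)
  if (!length(idx) || anyNA(idx)) {
    stop("eligible item pool is empty or references unknown items: bank exhausted",
         call. = FALSE)
  }
  M <- ctx$prior_precision + ctx$acc
  base_det <- det(M)
  dims <- bank$dimension[idx]
  info <- info3pl(bank$a[idx], bank$b[idx], bank$c[idx], cutoffs[dims],
                  scaling)
  # det(M + i e_d e_d') = det(M) + i * cofactor_dd(M) (matrix-determinant lemma)
  cof <- vapply(seq_len(ctx$D), function(d) {
    if (ctx$D == 1L) 1 else det(M[-d, -d, drop = FALSE])
  }, numeric(1L))
  dets <- base_det + info * cof[dims]
  ids <- bank$item_id[idx]
  min(ids[dets == max(dets)])
}
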