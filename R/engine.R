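# Test administration engine: the 5-step loop of item selection, response,
# MLE update, pre-rule evaluation and per-dimension decisions.
#
# For a fixed condition (bank, spec, pop) everything item-level is constant:
# item information at the cutoff vector, and each item's additive
# contribution to every dimension's log likelihood ratio under SPRT-SF and
# SPRT-C for either response.  condition_tables() precomputes these so a
# test step costs O(1) plus one bounded 1-D MLE update.

#' Precompute per-condition tables
#'
#' Precomputes, for a fixed bank / classification spec / population model:
#' item Fisher information at the cutoff vector, per-dimension selection
#' order, and each item's additive log-likelihood-ratio contribution under
#' SPRT-SF and SPRT-C for a correct and an incorrect response.  Passing the
#' result to [administer_examinee()] amortises this cost over a whole
#' simulated condition.
#'
#' @param bank An [item_bank()].
#' @param spec A [classification_spec()] with one cutoff per bank dimension.
#' @param pop A [population_model()].
#' @inheritParams prob_3pl
#' @return An opaque list of class `condition_tables`.
#' @export
condition_tables <- function(bank, spec, pop, scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  D <- attr(bank, "D")
  if (length(spec$cutoffs) != D) {
    stop("spec has ", length(spec$cutoffs), " cutoffs but bank has ", D,
         " dimensions", call. = FALSE)
  }
  a <- bank$a; b <- bank$b; cc <- bank$c
  dims <- bank$dimension
  info_cut <- info3pl(a, b, cc, spec$cutoffs[dims], scaling)
  # selection order per dimension: info at cutoff descending, id ascending
  ord <- lapply(seq_len(D), function(d) {
    i <- which(dims == d)
    i[order(-info_cut[i], bank$item_id[i])]
  })
  pU <- p3pl(a, b, cc, spec$theta_U[dims], scaling)
  pL <- p3pl(a, b, cc, spec$theta_L[dims], scaling)
  wsf1 <- log(pU) - log(pL)
  wsf0 <- log1p(-pU) - log1p(-pL)
  wc1 <- matrix(0, length(a), D)
  wc0 <- matrix(0, length(a), D)
  for (d in seq_len(D)) {
    thU <- thL <- numeric(length(a))
    for (q in seq_len(D)) {
      sel <- dims == q
      if (q == d) {
        thU[sel] <- spec$theta_U[[d]]
        thL[sel] <- spec$theta_L[[d]]
      } else {
        thU[sel] <- conditional_params(pop, d, spec$theta_U[[d]], q)$mean
        thL[sel] <- conditional_params(pop, d, spec$theta_L[[d]], q)$mean
      }
    }
    pUc <- p3pl(a, b, cc, thU, scaling)
    pLc <- p3pl(a, b, cc, thL, scaling)
    wc1[, d] <- log(pUc) - log(pLc)
    wc0[, d] <- log1p(-pUc) - log1p(-pLc)
  }
  structure(list(
    bank = bank, spec = spec, pop = pop, D = D,
    a = a, b = b, c = cc, dims = dims, item_id = bank$item_id,
    info_cut = info_cut, ord = ord, scaling = scaling,
    wsf1 = wsf1, wsf0 = wsf0, wc1 = wc1, wc0 = wc0,
    prior_precision = solve(pop$sigma)
  ), class = "condition_tables")
}

#' Administer a complete classification test to one examinee
#'
#' Runs the full administration loop: Segall item selection at the cutoff
#' vector, simulated 3PL response (drawn from the current RNG stream),
#' per-dimension MLE update, pre-rule evaluation (for the P-SPRT) and
#' interim decisions against the Wald thresholds, subject to the
#' per-dimension minimum and maximum test lengths.  A dimension reaching the
#' maximum undecided receives a forced classification.
#'
#' @param theta_true True latent trait vector.
#' @param bank,spec,pop Bank, classification spec and population model;
#'   ignored when `tables` is supplied.
#' @param criterion `"P"` (pre-rule switching), `"SF"` or `"C"`.
#' @param min_items,max_items Per-dimension minimum and maximum lengths
#'   (defaults 3 and 30).
#' @param tables Optional precomputed [condition_tables()].
#' @param trace If `TRUE`, attach a per-step trace data frame.
#' @inheritParams prob_3pl
#' @return An object of class `examinee_result`: a list with the true
#'   traits, per-dimension classifications and correctness, per-dimension
#'   and total lengths, forced flags, and optionally the trace.
#' @export
administer_examinee <- function(theta_true, bank = NULL, spec = NULL,
                                pop = NULL, criterion = c("P", "SF", "C"),
                                min_items = 3L, max_items = 30L,
                                tables = NULL, trace = FALSE,
                                scaling = DEFAULT_SCALING) {
  criterion <- match.arg(criterion)
  if (is.null(tables)) tables <- condition_tables(bank, spec, pop, scaling)
  spec <- tables$spec
  pop <- tables$pop
  D <- tables$D
  if (criterion == "P" && D != 2L) {
    stop("the P-SPRT pre-rule is defined for two dimensions", call. = FALSE)
  }
  if (length(theta_true) != D) stop("`theta_true` must have length ", D,
                                    call. = FALSE)
  n_per_dim <- lengths(tables$ord)
  if (any(n_per_dim < max_items)) {
    stop("bank has fewer than max_items items on some dimension",
         call. = FALSE)
  }
  ptr <- rep(1L, D)
  k <- integer(D)
  status <- rep("open", D)
  forced <- rep(FALSE, D)
  theta_hat <- numeric(D)
  llr_sf <- numeric(D)
  llr_c <- numeric(D)
  acc <- numeric(D)
  resp_row <- matrix(0L, max_items, D)
  resp_u <- matrix(0L, max_items, D)
  P <- tables$prior_precision
  trace_rows <- if (trace) vector("list", D * max_items)
  step <- 0L
  repeat {
    open <- status == "open"
    if (!any(open) && all(k >= min_items)) break
    elig <- which((open | k < min_items) & k < max_items)
    if (!length(elig)) break  # all remaining dims at max (handled by forcing)
    cand_row <- vapply(elig, function(d) tables$ord[[d]][ptr[[d]]], integer(1L))
    cand_info <- tables$info_cut[cand_row]
    # determinant of prior precision + accumulated + candidate info (all at
    # the cutoff vector); rank-1 diagonal update via the determinant lemma
    M <- P
    diag(M) <- diag(M) + acc
    base_det <- det(M)
    cof <- vapply(elig, function(d) {
      if (D == 1L) 1 else det(M[-d, -d, drop = FALSE])
    }, numeric(1L))
    dets <- base_det + cand_info * cof
    best <- which(dets == max(dets))
    if (length(best) > 1L) {
      best <- best[which.min(tables$item_id[cand_row[best]])]
    }
    d_star <- elig[[best]]
    row <- cand_row[[best]]
    ptr[[d_star]] <- ptr[[d_star]] + 1L
    p_true <- p3pl(tables$a[[row]], tables$b[[row]], tables$c[[row]],
                   theta_true[[d_star]], tables$scaling)
    u <- if (stats::runif(1L) < p_true) 1L else 0L
    k[[d_star]] <- k[[d_star]] + 1L
    resp_row[k[[d_star]], d_star] <- row
    resp_u[k[[d_star]], d_star] <- u
    acc[[d_star]] <- acc[[d_star]] + tables$info_cut[[row]]
    llr_sf[[d_star]] <- llr_sf[[d_star]] +
      if (u == 1L) tables$wsf1[[row]] else tables$wsf0[[row]]
    llr_c <- llr_c + if (u == 1L) tables$wc1[row, ] else tables$wc0[row, ]
    rows_d <- resp_row[seq_len(k[[d_star]]), d_star]
    theta_hat[[d_star]] <- mle_1d(tables$a[rows_d], tables$b[rows_d],
                                  tables$c[rows_d],
                                  resp_u[seq_len(k[[d_star]]), d_star],
                                  scaling = tables$scaling)
    ph <- if (criterion == "P") {
      pop$rho * prod(theta_hat - spec$cutoffs)
    } else NA_real_
    crit_used <- rep(NA_character_, D)
    for (d in which(status == "open")) {
      crit_d <- switch(criterion, SF = "SF", C = "C",
                       P = choose_criterion(ph))
      crit_used[[d]] <- crit_d
      llr <- if (crit_d == "C") llr_c[[d]] else llr_sf[[d]]
      dec <- if (k[[d]] >= min_items) {
        decide_log(llr, spec$log_A, spec$log_B)
      } else "continue"
      if (dec == "continue" && k[[d]] == max_items) {
        dec <- forced_decide_log(llr, spec$log_A, spec$log_B)
        forced[[d]] <- TRUE
      }
      if (dec != "continue") status[[d]] <- dec
    }
    step <- step + 1L
    if (trace) {
      trace_rows[[step]] <- data.frame(
        step = step, item_id = tables$item_id[[row]], dimension = d_star,
        u = u, t(stats::setNames(theta_hat, paste0("theta_hat", seq_len(D)))),
        phi = ph,
        t(stats::setNames(llr_sf, paste0("logLR_sf", seq_len(D)))),
        t(stats::setNames(llr_c, paste0("logLR_c", seq_len(D)))),
        t(stats::setNames(crit_used, paste0("criterion", seq_len(D)))),
        t(stats::setNames(status, paste0("status", seq_len(D))))
      )
    }
  }
  truth <- true_classification(theta_true, spec$cutoffs)
  structure(list(
    theta_true = theta_true,
    classification = status,
    truth = truth,
    correct = status == truth,
    lengths = k,
    total_length = sum(k),
    forced = forced,
    criterion = criterion,
    theta_hat = theta_hat,
    trace = if (trace) do.call(rbind, trace_rows[seq_len(step)])
  ), class = "examinee_result")
}

#' @export
print.examinee_result <- function(x, ...) {
  cat("<examinee_result> criterion ", x$criterion,
      "; classification (", paste(x$classification, collapse = ", "),
      "); correct (", paste(x$correct, collapse = ", "),
      "); lengths (", paste(x$lengths, collapse = ", "),
      "); forced (", paste(x$forced, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Construct a test state
#'
#' A running record of an administration: ordered responses, per-dimension
#' counts, provisional MLE traits and per-dimension statuses.  Used to
#' evaluate termination statistics outside the engine.
#'
#' @param bank An [item_bank()].
#' @param responses Data frame with columns `item_id` and `u`, in
#'   administration order.
#' @param theta_hat Provisional trait estimates; defaults to
#'   [mle_estimate()] on `responses`.
#' @param status Per-dimension status, `"open"`, `"above"` or `"below"`;
#'   defaults to all open.
#' @inheritParams prob_3pl
#' @return An object of class `test_state`.
#' @export
test_state <- function(bank, responses = data.frame(item_id = integer(),
                                                    u = integer()),
                       theta_hat = NULL, status = NULL,
                       scaling = DEFAULT_SCALING) {
  bank <- as_item_bank(bank)
  D <- attr(bank, "D")
  if (anyDuplicated(responses$item_id)) {
    stop("an item can be administered at most once", call. = FALSE)
  }
  m <- match_responses(responses, bank)
  if (!all(m$u %in% c(0L, 1L))) stop("responses must be 0/1", call. = FALSE)
  k <- tabulate(bank$dimension[m$idx], nbins = D)
  if (is.null(theta_hat)) {
    theta_hat <- mle_estimate(responses, bank, scaling = scaling)
  }
  if (is.null(status)) status <- rep("open", D)
  structure(list(bank = bank, responses = responses, k = k,
                 theta_hat = theta_hat, status = status, D = D),
            class = "test_state")
}

#' Evaluate termination statistics for every open dimension
#'
#' For each open dimension of a [test_state()], computes the pre-rule value
#' (for the P-SPRT), the criterion actually used, the log likelihood ratio
#' and the resulting decision.  Evaluation is gated to `"continue"` while a
#' dimension has fewer than `min_items` responses; a dimension at
#' `max_items` that would otherwise continue receives a forced decision.
#'
#' @param state A [test_state()].
#' @param spec A [classification_spec()].
#' @param pop A [population_model()]; required for criteria `"C"` and `"P"`.
#' @param criterion `"P"`, `"SF"` or `"C"`.
#' @param min_items,max_items Per-dimension length limits.
#' @inheritParams prob_3pl
#' @return A data frame with one row per open dimension: `dimension`, `k`,
#'   `phi`, `criterion_used`, `log_lr`, `decision`, `forced`.
#' @export
evaluate_termination <- function(state, spec, pop = NULL,
                                 criterion = c("P", "SF", "C"),
                                 min_items = 3L, max_items = 30L,
                                 scaling = DEFAULT_SCALING) {
  criterion <- match.arg(criterion)
  if (criterion != "SF" && is.null(pop)) {
    stop("`pop` is required for criteria C and P", call. = FALSE)
  }
  ph <- if (criterion == "P") {
    phi(pop$rho, state$theta_hat, spec$cutoffs)
  } else NA_real_
  open <- which(state$status == "open")
  out <- lapply(open, function(d) {
    crit_d <- switch(criterion, SF = "SF", C = "C", P = choose_criterion(ph))
    llr <- if (crit_d == "C") {
      lr_c(d, state$responses, state$bank, spec, pop, log = TRUE,
           scaling = scaling)
    } else {
      lr_sf(d, state$responses, state$bank, spec, log = TRUE,
            scaling = scaling)
    }
    dec <- if (state$k[[d]] >= min_items) {
      decide_log(llr, spec$log_A, spec$log_B)
    } else "continue"
    forced <- FALSE
    if (dec == "continue" && state$k[[d]] >= max_items) {
      dec <- forced_decide_log(llr, spec$log_A, spec$log_B)
      forced <- TRUE
    }
    data.frame(dimension = d, k = state$k[[d]], phi = ph,
               criterion_used = crit_d, log_lr = llr, decision = dec,
               forced = forced)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
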