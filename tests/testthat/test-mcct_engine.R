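# Full-administration engine: the selection / response / estimation /
# termination loop with length constraints.

tiny_setup <- function(rho = 0.5, cutoffs = c(0, 0), seed = 101) {
  list(bank = make_tiny_bank(seed),
       spec = classification_spec(cutoffs),
       pop = population_model(rho))
}

test_that("per-dimension lengths respect the minimum and maximum", {
  s <- tiny_setup()
  tab <- condition_tables(s$bank, s$spec, s$pop)
  set.seed(77)
  for (rep in 1:25) {
    th <- rnorm(2)
    res <- administer_examinee(th, criterion = "P", min_items = 3L,
                               max_items = 8L, tables = tab)
    expect_true(all(res$lengths >= 3L & res$lengths <= 8L))
    expect_identical(res$total_length, sum(res$lengths))
    expect_true(all(res$classification %in% c("above", "below")))
    expect_identical(res$correct,
                     res$classification ==
                       true_classification(th, s$spec$cutoffs))
  }
})

test_that("replaying a seed reproduces the full trajectory", {
  s <- tiny_setup()
  set.seed(4242)
  r1 <- administer_examinee(c(0.2, -0.1), s$bank, s$spec, s$pop,
                            criterion = "P", max_items = 8L, trace = TRUE)
  set.seed(4242)
  r2 <- administer_examinee(c(0.2, -0.1), s$bank, s$spec, s$pop,
                            criterion = "P", max_items = 8L, trace = TRUE)
  expect_identical(r1, r2)
})

test_that("rho 0 collapses SF, C and P to identical trajectories", {
  s <- tiny_setup(rho = 0)
  tab <- condition_tables(s$bank, s$spec, s$pop)
  for (rep in 1:10) {
    runs <- lapply(c("SF", "C", "P"), function(crit) {
      set.seed(1000 + rep)
      administer_examinee(c(rnorm(1), rnorm(1)), criterion = crit,
                          max_items = 10L, tables = tab, trace = TRUE)
    })
    expect_identical(runs[[1]]$trace$item_id, runs[[2]]$trace$item_id)
    expect_identical(runs[[1]]$trace$item_id, runs[[3]]$trace$item_id)
    expect_identical(runs[[1]]$classification, runs[[2]]$classification)
    expect_identical(runs[[1]]$classification, runs[[3]]$classification)
    expect_identical(runs[[1]]$lengths, runs[[3]]$lengths)
    # P-SPRT at rho 0 always falls back to SF
    cu <- c(runs[[3]]$trace$criterion1, runs[[3]]$trace$criterion2)
    expect_true(all(cu[!is.na(cu)] == "SF"))
  }
})

test_that("far-from-cutoff examinees classify above quickly", {
  # needs a bank rich enough near the cutoff that decisions by likelihood
  # ratio are reachable; 100 items per dimension suffices
  set.seed(55)
  s <- tiny_setup(rho = 0.5)
  bank <- generate_bank(100L, 2L)
  tab <- condition_tables(bank, s$spec, s$pop)
  set.seed(9)
  res <- replicate(30, {
    r <- administer_examinee(c(3, 3), criterion = "P", max_items = 15L,
                             tables = tab)
    c(both_above = all(r$classification == "above"), L = r$total_length)
  })
  expect_gte(mean(res["both_above", ]), 0.9)
  expect_lt(mean(res["L", ]), 26)  # clearly under the 30-item ceiling

  # length shrinks stochastically as traits move away from the cutoffs
  set.seed(10)
  near <- replicate(30, administer_examinee(c(0.2, 0.2), criterion = "P",
                                            max_items = 15L,
                                            tables = tab)$total_length)
  expect_gt(mean(near), mean(res["L", ]))
})

test_that("non-forced decisions sit beyond the Wald thresholds", {
  s <- tiny_setup(rho = 0.5)
  set.seed(55)
  bank <- generate_bank(100L, 2L)
  tab <- condition_tables(bank, s$spec, s$pop)
  set.seed(21)
  checked <- 0L
  for (rep in 1:10) {
    res <- administer_examinee(rnorm(2) + 1, criterion = "P",
                               max_items = 15L, tables = tab, trace = TRUE)
    tr <- res$trace
    for (d in 1:2) {
      st <- tr[[paste0("status", d)]]
      flip <- which(st != "open")[1]
      if (is.na(flip) || res$forced[d]) next
      crit <- tr[[paste0("criterion", d)]][flip]
      llr <- tr[[paste0("logLR_", tolower(crit), d)]][flip]
      if (st[flip] == "above") expect_gte(llr, s$spec$log_A)
      else expect_lt(llr, s$spec$log_B)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 5L)  # the assertion above must actually have run
})

test_that("evaluate_termination gates on the minimum and flags forcing", {
  s <- tiny_setup(rho = 0.8)
  # two dimension-1 items: below the 3-item minimum -> continue regardless
  st <- test_state(s$bank, data.frame(item_id = s$bank$item_id[1:2],
                                      u = c(1, 1)))
  ev <- evaluate_termination(st, s$spec, s$pop, "P")
  expect_identical(ev$decision, c("continue", "continue"))

  # phi > 0 records criterion C; phi <= 0 records SF
  st_pos <- test_state(s$bank, theta_hat = c(1, 1))
  expect_true(all(evaluate_termination(st_pos, s$spec, s$pop,
                                       "P")$criterion_used == "C"))
  st_neg <- test_state(s$bank, theta_hat = c(1, -1))
  expect_true(all(evaluate_termination(st_neg, s$spec, s$pop,
                                       "P")$criterion_used == "SF"))

  # at the maximum length an undecided dimension is force-classified
  d1 <- s$bank$item_id[s$bank$dimension == 1][1:4]
  st_max <- test_state(s$bank, data.frame(item_id = d1, u = c(1, 0, 1, 0)))
  ev <- evaluate_termination(st_max, s$spec, s$pop, "SF", max_items = 4L)
  row1 <- ev[ev$dimension == 1, ]
  expect_true(row1$forced)
  expect_true(row1$decision %in% c("above", "below"))
})

test_that("engine decisions match step-by-step public evaluation", {
  s <- tiny_setup(rho = 0.8)
  set.seed(63)
  res <- administer_examinee(c(0.8, 0.5), s$bank, s$spec, s$pop,
                             criterion = "P", max_items = 8L, trace = TRUE)
  tr <- res$trace
  for (step in seq_len(nrow(tr))) {
    resp <- data.frame(item_id = tr$item_id[1:step], u = tr$u[1:step])
    prev_status <- if (step == 1) c("open", "open") else {
      c(tr$status1[step - 1], tr$status2[step - 1])
    }
    st <- test_state(s$bank, resp, status = prev_status)
    ev <- evaluate_termination(st, s$spec, s$pop, "P", max_items = 8L)
    for (i in seq_len(nrow(ev))) {
      d <- ev$dimension[i]
      expect_equal(ev$phi[i], tr$phi[step], tolerance = 1e-9)
      expect_identical(ev$criterion_used[i],
                       tr[[paste0("criterion", d)]][step])
      ref_llr <- tr[[paste0("logLR_",
                            tolower(ev$criterion_used[i]), d)]][step]
      expect_equal(ev$log_lr[i], ref_llr, tolerance = 1e-9)
      expect_identical(ev$decision[i] != "continue",
                       tr[[paste0("status", d)]][step] != "open")
    }
  }
})

test_that("impossible configurations are rejected", {
  s <- tiny_setup()
  expect_error(administer_examinee(c(0, 0), s$bank, s$spec, s$pop,
                                   max_items = 25L), "fewer than max_items")
  expect_error(administer_examinee(0, s$bank, s$spec, s$pop,
                                   max_items = 8L), "length 2")
})
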