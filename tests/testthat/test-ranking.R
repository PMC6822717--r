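test_that("Cochran's Q matches the hand-evaluated fixed-effect formulas", {
  # homogeneity: equal estimates give Q = 0, P = 1
  h <- cochran_q(c(0.3, 0.3), c(0.07, 0.07))
  expect_equal(h$Q, 0)
  expect_equal(h$p, 1)

  # worked pair: w = 400 each, pooled 0, Q = 400*0.01*2 = 8
  q <- cochran_q(c(0.1, -0.1), c(0.05, 0.05))
  expect_equal(q$Q, 8, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  expect_equal(q$p, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(q$p, 5), 0.00468)

  # weight scaling law: scaling SEs by 10 divides Q by 100
  q10 <- cochran_q(c(0.1, -0.1), c(0.5, 0.5))
  expect_equal(q10$Q, 8 / 100, tolerance = 1e-12)
  expect_gt(q10$p, q$p)

  # invariant to stratum order and to shifting all estimates
  expect_equal(cochran_q(c(-0.1, 0.1), c(0.05, 0.05))$Q, q$Q)
  expect_equal(cochran_q(c(0.1, -0.1) + 5, c(0.05, 0.05))$Q, q$Q,
               tolerance = 1e-9)

  expect_error(cochran_q(0.1, 0.05), "2 strata")
  expect_error(cochran_q(c(0.1, 0.2), c(0.05, 0)), "positive")
  expect_error(cochran_q(c(0.1, 0.2), 0.05), "length")
})

test_that("threshold arithmetic is exact", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 16692), 0.05 / 16692)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("step-up selection matches exhaustive rank enumeration", {
  sel <- fdr_select(c(0.001, 0.2), n_tests = 2)
  expect_identical(sel$k, 1L)
  expect_equal(sel$hits, 0.001)
  expect_equal(sel$threshold, 0.025)

  withr::with_seed(51, {
    for (i in seq_len(200)) {
      m <- sample(1:50, 1)
      p <- runif(m)^sample(c(1, 3), 1)  # occasionally enriched near zero
      n_tests <- m + sample(0:5, 1)
      sel <- fdr_select(p, alpha = 0.05, n_tests = n_tests)
      expect_identical(sel$k, brute_force_fdr_k(p, 0.05, n_tests))
    }
  })

  # strict inequality: a P value exactly at the threshold does not count
  expect_identical(fdr_select(c(0.05), n_tests = 1)$k, 0L)
  expect_identical(fdr_select(c(0.049999), n_tests = 1)$k, 1L)

  # k = 0 reports a not-applicable threshold
  empty <- fdr_select(c(0.5, 0.9), n_tests = 2)
  expect_identical(empty$k, 0L)
  expect_true(is.na(empty$threshold))
  expect_identical(length(empty$hits), 0L)

  expect_error(fdr_select(c(0, 0.5)), "P values")
  expect_error(fdr_select(c(0.5), n_tests = 0), "n_tests")
})

test_that("interaction ranking restricts to shared scalar tests and sorts by Q P value", {
  mk_scan <- function(ids, est, se, type = "linear",
                      dt = "continuous", stratum = "ever") {
    structure(tibble::tibble(outcome_id = ids, data_type = dt, test = type,
                             estimate = est, se = se,
                             p = 2 * pnorm(-abs(est / se)),
                             n = 1000L, converged = TRUE),
              stratum = stratum, class = c("phewas_scan", "tbl_df", "tbl",
                                           "data.frame"))
  }
  ever <- mk_scan(c("a", "b", "c"), c(0.5, 0.0, 0.2), c(0.05, 0.05, 0.05))
  never <- mk_scan(c("a", "b"), c(0.0, 0.0), c(0.05, 0.05),
                   stratum = "never")
  rk <- interaction_ranking(ever, never)
  # outcome c testable only in ever smokers is absent
  expect_setequal(rk$outcome_id, c("a", "b"))
  expect_identical(rk$outcome_id[1], "a")  # strongest interaction first
  expect_identical(attr(rk, "n_tests"), 2L)
  expect_equal(rk$Q[rk$outcome_id == "a"],
               cochran_q(c(0.5, 0), c(0.05, 0.05))$Q)

  # identical scans give all-zero Q
  self <- interaction_ranking(ever, ever)
  expect_true(all(self$Q < 1e-20))

  # multinomial rows (no scalar estimate) are excluded
  ever2 <- ever; never2 <- never
  ever2$estimate[1] <- NA; ever2$se[1] <- NA
  expect_setequal(interaction_ranking(ever2, never2)$outcome_id, "b")

  expect_error(interaction_ranking(mk_scan("z", 1, 1), never),
               "no outcome")
})

test_that("two-step selection reuses whole-sample hits at a reduced n", {
  mk <- function(ids, est, se, stratum) {
    structure(tibble::tibble(outcome_id = ids, data_type = "continuous",
                             test = "linear", estimate = est, se = se,
                             p = 2 * pnorm(-abs(est / se)), n = 1000L,
                             converged = TRUE),
              stratum = stratum,
              class = c("phewas_scan", "tbl_df", "tbl", "data.frame"))
  }
  ids <- sprintf("o%02d", 1:20)
  withr::with_seed(52, {
    est_full <- c(rep(0.5, 3), rnorm(17, 0, 0.02))
    est_ever <- c(1.0, 0.5, 0.5, rnorm(17, 0, 0.02))
    est_never <- c(0.0, 0.5, 0.5, rnorm(17, 0, 0.02))
  })
  full <- mk(ids, est_full, 0.05, "full")
  ever <- mk(ids, est_ever, 0.05, "ever")
  never <- mk(ids, est_never, 0.05, "never")
  ts <- two_step_interaction(full, ever, never)
  expect_s3_class(ts, "gxe_two_step")
  expect_gte(ts$step1$k, 3L)
  # step 2 n equals the step-1 hits possessing an interaction P
  expect_identical(ts$step2$n_tests, nrow(ts$table))
  # the qualitative interaction survives both steps
  expect_identical(ts$table$outcome_id[1], "o01")
  expect_gte(ts$step2$k, 1L)
  # step-2 threshold arithmetic: alpha * k / n at the reduced n
  expect_equal(ts$step2$threshold, 0.05 * ts$step2$k / ts$step2$n_tests)

  # a null phenome yields an empty step 1
  null_scan <- mk(ids, rep(0, 20), 0.05, "full")
  null_scan$p <- rep(0.9, 20)
  ts0 <- two_step_interaction(null_scan, ever, never)
  expect_identical(ts0$step1$k, 0L)
  expect_null(ts0$table)
})

test_that("QQ data pairs observed with uniform order statistics", {
  # single P = 0.05: expected -log10 = log10(2), observed ~ 1.301
  qq1 <- qq_data(0.05)
  expect_equal(qq1$expected, log10(2), tolerance = 1e-12)
  expect_equal(qq1$observed, -log10(0.05), tolerance = 1e-12)

  withr::with_seed(53, {
    p <- runif(2000)
    qq <- qq_data(p)
    expect_identical(nrow(qq), 2000L)
    # null calibration: points hug the identity line
    expect_lt(max(abs(10^(-qq$observed) - 10^(-qq$expected))),
              1.63 / sqrt(2000))  # KS bound at alpha = 0.01
    expect_equal(attr(qq, "bonferroni"), 0.05 / 2000)

    # injected signal lifts only the upper tail
    p_sig <- c(rep(1e-10, 10), runif(1990))
    qs <- qq_data(p_sig)
    expect_gt(qs$observed[1] - qs$expected[1], 5)
    expect_lt(abs(qs$observed[1500] - qs$expected[1500]), 0.2)
  })
  expect_error(qq_data(numeric()), "no P values")
})
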