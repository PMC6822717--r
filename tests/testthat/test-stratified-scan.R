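test_that("continuous estimates equal the Frisch-Waugh partialled-out OLS coefficient", {
  withr::with_seed(31, {
    n <- 400
    g <- rbinom(n, 2, 0.33)
    C <- cbind(age = runif(n, 40, 69), sex = rbinom(n, 1, 0.5),
               pc1 = rnorm(n))
    y <- 0.1 * g + 0.01 * C[, "age"] + rnorm(n)
    fit <- fit_association(y, "continuous", g, C)
    oracle <- oracle_fw_coefficient(y, g, C)
    expect_equal(fit$estimate, oracle, tolerance = 1e-8)
    # and equals lm() exactly
    lmfit <- summary(lm(y ~ C + g))
    expect_equal(fit$estimate, lmfit$coefficients["g", 1], tolerance = 1e-10)
    expect_equal(fit$se, lmfit$coefficients["g", 2], tolerance = 1e-10)
    expect_equal(fit$p, lmfit$coefficients["g", 4], tolerance = 1e-10)
  })
})

test_that("logistic, ordered and multinomial fits match brute-force likelihood maximization", {
  withr::with_seed(32, {
    n <- 180
    g <- rbinom(n, 2, 0.4)
    x <- rnorm(n)
    X <- cbind(1, x, g)

    yb <- rbinom(n, 1, plogis(-0.3 + 0.4 * g + 0.2 * x))
    fit_b <- fit_association(yb, "binary", g, cbind(x = x))
    beta_oracle <- oracle_logistic(yb, X)
    expect_equal(fit_b$estimate, beta_oracle[3], tolerance = 1e-4)

    latent <- 0.5 * g + rlogis(n)
    yo <- cut(latent, c(-Inf, 0.3, 1.4, Inf), labels = FALSE)
    fit_o <- fit_association(factor(yo, ordered = TRUE), "ordered", g,
                             cbind(x = x))
    polr_oracle <- oracle_polr(yo, cbind(x, g), K = 3)
    expect_equal(fit_o$estimate, unname(polr_oracle$beta[2]),
                 tolerance = 1e-4)

    yu <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
    fit_u <- fit_association(factor(yu), "unordered", g, cbind(x = x))
    dev1 <- oracle_multinom_deviance(yu, X)
    dev0 <- oracle_multinom_deviance(yu, cbind(1, x))
    p_oracle <- pchisq(dev0 - dev1, df = 2, lower.tail = FALSE)
    expect_true(is.na(fit_u$estimate))
    expect_equal(fit_u$p, p_oracle, tolerance = 1e-4)
  })
})

test_that("adding an irrelevant covariate barely moves the dosage estimate", {
  withr::with_seed(33, {
    n <- 30000
    g <- rbinom(n, 2, 0.33)
    y <- 0.1 * g + rnorm(n)
    junk <- rnorm(n)  # uncorrelated with instrument and outcome
    f0 <- fit_association(y, "continuous", g)
    f1 <- fit_association(y, "continuous", g, cbind(junk = junk))
    expect_lt(abs(f0$estimate - f1$estimate), 0.5 * f0$se)
  })
})

test_that("phenome scan tests everything testable and explains exclusions", {
  cfg <- population_config(n_participants = 4000, or_snp_status = 1)
  specs <- list(
    outcome_spec("201", "continuous", effect_ever = 0.2),
    outcome_spec("202", "binary", prevalence = 0.3),
    outcome_spec("203", "ordered", n_categories = 3),
    # rare binary outcome: fails the 10-per-category filter in strata
    outcome_spec("204", "binary", prevalence = 0.002),
    # heavily missing outcome: fails the 500 rule in strata
    outcome_spec("205", "continuous", missingness = 0.9))
  bb <- simulate_biobank(cfg, specs, seed = 41)
  derived <- derive_outcomes(bb$phenotypes, bb$metadata, seed = 1)

  scan_e <- run_phenome_scan(bb, derived, stratum = "ever")
  scan_n <- run_phenome_scan(bb, derived, stratum = "never")
  scan_f <- run_phenome_scan(bb, derived, stratum = "full")

  expect_s3_class(scan_e, "phewas_scan")
  expect_true(all(c("201", "202", "203") %in% scan_e$outcome_id))
  # filter asymmetry: excluded outcomes carry reasons in that stratum
  exc <- attr(scan_e, "excluded")
  expect_true("205" %in% exc$outcome_id)
  # full-sample scan may still test what strata cannot
  expect_true(nrow(scan_f) >= nrow(scan_e))
  # rerun is byte-identical
  scan_e2 <- run_phenome_scan(bb, derived, stratum = "ever")
  expect_identical(tibble::as_tibble(scan_e), tibble::as_tibble(scan_e2))
  # empty stratum errors
  bb$phenotypes$smoking_status[] <- "ever"
  expect_error(run_phenome_scan(bb$phenotypes, derived, stratum = "never"),
               "empty")
})

test_that("the shared-QR block path equals per-outcome lm fits exactly", {
  withr::with_seed(34, {
    n <- 500
    g <- rbinom(n, 2, 0.33)
    C <- cbind(age = runif(n), sex = rbinom(n, 1, 0.5))
    Y <- matrix(rnorm(n * 5), n, 5)
    Y[, 1] <- Y[, 1] + 0.3 * g
    block <- run_matrix_scan(Y, g, covariates = C)
    for (j in 1:5) {
      sm <- summary(lm(Y[, j] ~ C + g))$coefficients
      expect_equal(block$estimate[j], sm["g", 1], tolerance = 1e-10)
      expect_equal(block$se[j], sm["g", 2], tolerance = 1e-10)
      expect_equal(block$p[j], sm["g", 4], tolerance = 1e-10)
    }
  })
})

test_that("rank-deficient covariates raise an error naming the columns", {
  withr::with_seed(35, {
    n <- 200
    g <- rbinom(n, 2, 0.3)
    x <- rnorm(n)
    C <- cbind(a = x, b = 2 * x)
    expect_error(fit_association(rnorm(n), "continuous", g, C),
                 "collinear")
  })
})

test_that("null binary outcomes give calibrated Wald P values", {
  # type-I error calibration: P values from instrument-orthogonal binary
  # outcomes are uniform
  withr::with_seed(36, {
    n <- 700
    g <- rbinom(n, 2, 0.33)
    pvals <- vapply(seq_len(400), function(i) {
      y <- rbinom(n, 1, 0.3)
      fit_association(y, "binary", g)$p
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  })
})
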