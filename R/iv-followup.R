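#' Unweighted allele score over a SNP panel
#'
#' Per-participant sum of effect-allele dosages across the panel.  SNPs whose
#' stored dosage counts the effect-decreasing allele are flipped
#' (`dosage -> 2 - dosage`) before summation; no weighting by effect size is
#' applied.  A participant with any missing dosage gets a missing score (no
#' imputation).
#'
#' @param dosages Numeric matrix (participants x SNPs) with entries in
#'   \[0, 2\].
#' @param flipped Logical vector, one per SNP: `TRUE` when the stored allele
#'   is the effect-decreasing one.
#'
#' @return Numeric vector of scores in \[0, 2 * ncol(dosages)\].
#' @export
#' @examples
#' build_allele_score(rbind(c(2, 1, 0)), c(FALSE, FALSE, FALSE))  # 3
build_allele_score <- function(dosages, flipped = NULL) {
  dosages <- as.matrix(dosages)
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    abort("dosages must lie in [0, 2]")
  }
  if (is.null(flipped)) flipped <- rep(FALSE, ncol(dosages))
  stopifnot(length(flipped) == ncol(dosages))
  if (any(flipped)) {
    dosages[, flipped] <- 2 - dosages[, flipped]
  }
  rowSums(dosages)
}

#' Instrument-strength regression with bootstrap confidence interval
#'
#' Ordinary least squares of the (standardized) exposure on the
#' (standardized) allele score plus covariates, reporting the SD change in
#' exposure per SD of score.  Confidence intervals come from a percentile
#' case-resampling bootstrap, which is valid under the non-normal residuals
#' typical of composite exposure indices.
#'
#' @param data Data frame holding the variables.
#' @param exposure,score Column names of the exposure and the allele score.
#' @param covariates Character vector of covariate column names.
#' @param n_boot Number of bootstrap resamples (1000 by default).
#' @param level Confidence level.
#' @param seed Optional integer seed.
#'
#' @return A list of class `iv_strength`: `estimate`, `conf_low`,
#'   `conf_high`, `n`, `n_boot`, `f_statistic` (first-stage partial F).
#' @export
instrument_strength <- function(data, exposure, score, covariates = NULL,
                                n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(is.data.frame(data))
  n_boot <- check_count(n_boot, "n_boot")
  vars <- c(exposure, score, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not in data: ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[vars]), vars]
  if (sd(d[[score]]) == 0) abort("allele score has zero variance")
  d[[exposure]] <- as.numeric(scale(d[[exposure]]))
  d[[score]] <- as.numeric(scale(d[[score]]))
  X <- cbind(`(Intercept)` = 1,
             if (length(covariates)) as.matrix(d[covariates]) else NULL,
             score = d[[score]])
  fit <- linear_block_fit(X, matrix(d[[exposure]], ncol = 1), focal = "score")
  f_stat <- (fit$estimate / fit$se)^2
  if (n_boot < 2) {
    warn("n_boot < 2: degenerate interval equal to the point estimate")
    ci <- c(fit$estimate, fit$estimate)
  } else {
    boots <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        linear_block_fit(X[idx, , drop = FALSE],
                         matrix(d[[exposure]][idx], ncol = 1),
                         focal = "score")$estimate
      }, numeric(1))
    })
    ci <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
  }
  structure(list(estimate = fit$estimate, conf_low = ci[1], conf_high = ci[2],
                 p = fit$p, n = nrow(d), n_boot = n_boot,
                 f_statistic = unname(f_stat)),
            class = "iv_strength")
}

#' @export
print.iv_strength <- function(x, ...) {
  cat(sprintf(
    "Instrument strength: %.4f SD exposure per SD score [%.4f, %.4f] (n = %d, first-stage F = %.0f)\n",
    x$estimate, x$conf_low, x$conf_high, x$n, x$f_statistic))
  invisible(x)
}

#' @method tidy iv_strength
#' @export
tidy.iv_strength <- function(x, ...) {
  tibble::tibble(term = "score", estimate = x$estimate,
                 conf.low = x$conf_low, conf.high = x$conf_high,
                 p.value = x$p)
}

#' @method glance iv_strength
#' @export
glance.iv_strength <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, f_statistic = x$f_statistic)
}

probit_to_odds <- function(b) exp(1.6 * b)

#' Two-stage instrumental-variable probit regression
#'
#' Stage one regresses the exposure on the instrument (plus covariates) by
#' ordinary least squares; stage two fits a probit model of the binary
#' outcome on the stage-one fitted exposure (plus covariates).  The probit
#' coefficient b is converted to an approximate odds ratio as `exp(1.6 * b)`
#' (the logit and probit scales differ by a factor of about 1.6).
#' Confidence intervals are percentile bootstrap over case resampling of the
#' entire two-stage procedure.
#'
#' @param data Data frame holding the variables.
#' @param outcome Column name of the binary (0/1) outcome.
#' @param exposure,instrument Column names; both are standardized in-sample
#'   so estimates are per SD.
#' @param covariates Character vector of covariate column names.
#' @param n_boot Number of bootstrap resamples (1000 by default).
#' @param level Confidence level.
#' @param seed Optional integer seed.
#'
#' @return A list of class `iv_probit`: `probit_estimate`, `odds_ratio`
#'   (`exp(1.6 b)`), their percentile CIs, `first_stage` (coefficient and F),
#'   `n`, `n_boot`.
#' @export
iv_probit <- function(data, outcome, exposure, instrument, covariates = NULL,
                      n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(is.data.frame(data))
  n_boot <- check_count(n_boot, "n_boot")
  vars <- c(outcome, exposure, instrument, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not in data: ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[vars]), vars]
  yv <- d[[outcome]]
  if (!all(yv %in% c(0, 1))) abort("outcome must be binary 0/1")
  d[[exposure]] <- as.numeric(scale(d[[exposure]]))
  d[[instrument]] <- as.numeric(scale(d[[instrument]]))

  two_stage <- function(dd) {
    Cm <- if (length(covariates)) as.matrix(dd[covariates]) else NULL
    X1 <- cbind(`(Intercept)` = 1, Cm, iv = dd[[instrument]])
    qr1 <- qr(X1)
    beta1 <- qr.coef(qr1, dd[[exposure]])
    fitted <- drop(X1 %*% beta1)
    df2 <- data.frame(.y = dd[[outcome]], .xhat = fitted)
    rhs <- ".xhat"
    if (!is.null(Cm)) {
      df2 <- cbind(df2, as.data.frame(Cm))
      rhs <- paste(c(colnames(Cm), ".xhat"), collapse = " + ")
    }
    fit2 <- glm(as.formula(paste(".y ~", rhs)), data = df2,
                family = binomial(link = "probit"))
    if (!fit2$converged) abort("probit stage did not converge")
    c(first = unname(beta1["iv"]), probit = unname(coef(fit2)[".xhat"]))
  }

  est <- two_stage(d)
  # first-stage strength (t of the instrument in stage one)
  Cm <- if (length(covariates)) as.matrix(d[covariates]) else NULL
  X1 <- cbind(`(Intercept)` = 1, Cm, iv = d[[instrument]])
  fs <- linear_block_fit(X1, matrix(d[[exposure]], ncol = 1), focal = "iv")
  if (abs(fs$estimate / fs$se) < 2) {
    warn("weak instrument: first-stage |t| < 2")
  }
  boots <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      tryCatch(two_stage(d[idx, ])[["probit"]], error = function(e) NA_real_)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci_b <- if (length(boots) >= 2) quantile(boots, probs, names = FALSE) else {
    warn("degenerate bootstrap interval")
    rep(est[["probit"]], 2)
  }
  structure(
    list(probit_estimate = est[["probit"]],
         probit_conf_low = ci_b[1], probit_conf_high = ci_b[2],
         odds_ratio = probit_to_odds(est[["probit"]]),
         odds_conf_low = probit_to_odds(ci_b[1]),
         odds_conf_high = probit_to_odds(ci_b[2]),
         first_stage = list(estimate = fs$estimate, se = fs$se,
                            f_statistic = unname((fs$estimate / fs$se)^2)),
         n = nrow(d), n_boot = n_boot),
    class = "iv_probit")
}

#' @export
print.iv_probit <- function(x, ...) {
  cat(sprintf(
    "Two-stage IV probit (n = %d, %d bootstraps)\n  probit estimate per SD exposure: %.4f [%.4f, %.4f]\n  odds scale exp(1.6 b): %.3f [%.3f, %.3f]\n",
    x$n, x$n_boot, x$probit_estimate, x$probit_conf_low, x$probit_conf_high,
    x$odds_ratio, x$odds_conf_low, x$odds_conf_high))
  invisible(x)
}

#' @method tidy iv_probit
#' @export
tidy.iv_probit <- function(x, ...) {
  tibble::tibble(
    term = c("exposure (probit)", "exposure (odds)"),
    estimate = c(x$probit_estimate, x$odds_ratio),
    conf.low = c(x$probit_conf_low, x$odds_conf_low),
    conf.high = c(x$probit_conf_high, x$odds_conf_high))
}

#' @method glance iv_probit
#' @export
glance.iv_probit <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot,
                 first_stage_f = x$first_stage$f_statistic)
}

#' Ordered-logistic follow-up of a single identified outcome
#'
#' Re-examines one ordered categorical outcome outside the automated scan:
#' proportional-odds regressions of the outcome on the instrument within the
#' ever and never strata under both the main covariate set (age, sex, 10
#' principal components) and a sensitivity set (40 principal components when
#' available), with Cochran's Q interaction P between the strata.
#'
#' @param data Participant table.
#' @param outcomes A [derive_outcomes()] tibble containing the outcome.
#' @param outcome_id Identifier of the ordered outcome to follow up.
#' @param covariate_sets Named list of covariate-name vectors; defaults to a
#'   `main` set (age, sex, pc1..pc10) and, when 40 PCs exist in the data, a
#'   `sensitivity` set with all 40.
#' @param instrument,stratum_var Column names, as in [run_phenome_scan()].
#'
#' @return A tibble, one row per (covariate set, stratum): estimate (log odds
#'   of a higher category per allele), SE, 95% CI, P, N, plus the interaction
#'   P of the covariate set.
#' @export
ordered_logistic_followup <- function(data, outcomes, outcome_id,
                                      covariate_sets = NULL,
                                      instrument = "snp",
                                      stratum_var = "smoking_status") {
  if (inherits(data, "synthetic_biobank")) data <- data$phenotypes
  row <- which(outcomes$outcome_id == outcome_id)
  if (length(row) != 1L) abort(sprintf("outcome '%s' not found", outcome_id))
  if (outcomes$data_type[row] != "ordered") {
    abort("follow-up is defined for ordered categorical outcomes")
  }
  if (is.null(covariate_sets)) {
    pcs <- grep("^pc[0-9]+$", names(data), value = TRUE)
    pcs <- pcs[order(as.integer(sub("pc", "", pcs)))]
    covariate_sets <- list(main = c("age", "sex", head(pcs, 10)))
    if (length(pcs) >= 40) {
      covariate_sets$sensitivity <- c("age", "sex", head(pcs, 40))
    }
  }
  out <- list()
  for (set_name in names(covariate_sets)) {
    cov <- intersect(covariate_sets[[set_name]], names(data))
    fits <- list()
    for (st in c("ever", "never")) {
      mask <- !is.na(data[[stratum_var]]) & data[[stratum_var]] == st
      fit <- fit_association(outcomes$values[[row]][mask], "ordered",
                             data[[instrument]][mask],
                             data[mask, cov, drop = FALSE])
      fits[[st]] <- dplyr::bind_cols(
        tibble::tibble(covariate_set = set_name, stratum = st), fit)
    }
    both <- dplyr::bind_rows(fits)
    q <- cochran_q(both$estimate, both$se)
    both$p_interaction <- q$p
    out[[set_name]] <- both
  }
  res <- dplyr::bind_rows(out)
  res$conf_low <- res$estimate - 1.96 * res$se
  res$conf_high <- res$estimate + 1.96 * res$se
  res$odds_ratio <- exp(res$estimate)
  res[, c("covariate_set", "stratum", "estimate", "se", "conf_low",
          "conf_high", "odds_ratio", "p", "n", "p_interaction")]
}
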