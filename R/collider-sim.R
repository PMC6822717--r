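#' Configuration for the collider-bias simulation studies
#'
#' Parameterizes the data-generating process used to quantify how much
#' stratifying on a phenotype the instrument affects (here: ever-smoking)
#' can bias per-stratum instrument-outcome estimates, and how much it can
#' inflate the false discovery rate of a null phenome scan.  A standard
#' normal confounder U affects both smoking status (odds ratio
#' `or_conf_status` per SD, additively with the SNP on the log-odds scale)
#' and each outcome (explaining `r2_conf_outcome` of its variance, with sign
#' `conf_sign`); conditioning on status then opens a non-causal path between
#' the SNP and the outcomes.
#'
#' @param n Cohort size (default: UK-Biobank scale).
#' @param allele_freq Instrument effect-allele frequency.
#' @param ever_prevalence Marginal prevalence of the ever stratum.
#' @param or_snp_status SNP odds ratio per allele on ever-smoking.
#' @param or_conf_status Confounder odds ratio per SD on ever-smoking.
#' @param r2_conf_outcome Fraction of each outcome's variance explained by
#'   the confounder, in \[0, 1).
#' @param conf_sign Sign (+1/-1) of the confounder effect on the outcome.
#' @param snp_outcome_effect Direct SNP effect on the outcome (0 under the
#'   null).
#' @param outcome_kind `"continuous"` or `"ordinal"` (a three-category
#'   facial-aging-like outcome obtained by cutting the continuous liability).
#' @param ordinal_props Marginal category proportions for the ordinal
#'   outcome (free parameters; defaults are a plausible facial-aging split).
#' @param n_outcomes Number of null outcomes in the FDR-inflation study.
#' @param n_reps Number of simulation replicates.
#'
#' @return A list of class `collider_sim_config`.
#' @export
collider_config <- function(n = 334968, allele_freq = 0.33,
                            ever_prevalence = 0.452, or_snp_status = 0.98,
                            or_conf_status = 100, r2_conf_outcome = 0.2,
                            conf_sign = 1, snp_outcome_effect = 0,
                            outcome_kind = c("continuous", "ordinal"),
                            ordinal_props = c(0.55, 0.40, 0.05),
                            n_outcomes = 1000, n_reps = 100) {
  n <- check_count(n, "n")
  check_probability(allele_freq, "allele_freq")
  check_probability(ever_prevalence, "ever_prevalence")
  check_positive(or_snp_status, "or_snp_status")
  check_positive(or_conf_status, "or_conf_status")
  check_probability(r2_conf_outcome, "r2_conf_outcome", open = FALSE)
  if (r2_conf_outcome >= 1) abort("`r2_conf_outcome` must be < 1")
  if (!conf_sign %in% c(-1, 1)) abort("`conf_sign` must be +1 or -1")
  outcome_kind <- match.arg(outcome_kind)
  if (any(diff(cumsum(ordinal_props)) <= 0) || any(ordinal_props <= 0) ||
      abs(sum(ordinal_props) - 1) > 1e-8) {
    abort("`ordinal_props` must be positive proportions summing to 1")
  }
  structure(
    list(n = n, allele_freq = allele_freq,
         ever_prevalence = ever_prevalence, or_snp_status = or_snp_status,
         or_conf_status = or_conf_status, r2_conf_outcome = r2_conf_outcome,
         conf_sign = conf_sign, snp_outcome_effect = snp_outcome_effect,
         outcome_kind = outcome_kind, ordinal_props = ordinal_props,
         n_outcomes = check_count(n_outcomes, "n_outcomes"),
         n_reps = check_count(n_reps, "n_reps")),
    class = "collider_sim_config")
}

#' Simulate one population under the collider data-generating process
#'
#' Draws genotypes under Hardy-Weinberg, a standard-normal confounder, smoking
#' status from a logistic model in dosage and confounder (intercept calibrated
#' by bisection to the marginal prevalence), and a continuous outcome
#' \eqn{Y = s\sqrt{r^2}\,U + \beta G + \sqrt{1 - r^2}\,\epsilon}, which has
#' unit marginal variance under the null.  For the ordinal kind, Y serves as
#' the latent liability and is cut at standard-normal quantiles of the
#' configured marginal proportions.
#'
#' @param config A [collider_config()].
#' @param seed Optional integer seed.
#'
#' @return A tibble with `snp`, `confounder`, `smoking_status` and `y`
#'   (numeric, or ordered factor for the ordinal kind; the latent liability
#'   is then kept as `y_latent`).
#' @export
simulate_collider_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "collider_sim_config"))
  with_seed_if(seed, {
    n <- config$n
    g <- rbinom(n, 2L, config$allele_freq)
    u <- rnorm(n)
    offset <- log(config$or_snp_status) * g + log(config$or_conf_status) * u
    a <- calibrate_intercept(offset, config$ever_prevalence)
    ever <- rbinom(n, 1L, plogis(a + offset)) == 1L
    r2 <- config$r2_conf_outcome
    y <- config$conf_sign * sqrt(r2) * u + config$snp_outcome_effect * g +
      sqrt(1 - r2) * rnorm(n)
    out <- tibble::tibble(
      snp = g, confounder = u,
      smoking_status = factor(ifelse(ever, "ever", "never"),
                              levels = c("never", "ever")))
    if (config$outcome_kind == "ordinal") {
      cuts <- qnorm(cumsum(config$ordinal_props))
      k <- length(config$ordinal_props)
      out$y_latent <- y
      out$y <- factor(findInterval(y, cuts[-k]) + 1L,
                      levels = seq_len(k), ordered = TRUE)
    } else {
      out$y <- y
    }
    out
  })
}

fit_collider_stratum <- function(pop, stratum, ordinal) {
  rows <- pop$smoking_status == stratum
  if (ordinal) {
    df <- data.frame(y = droplevels(pop$y[rows]), snp = pop$snp[rows])
    fit <- tryCatch(
      suppressWarnings(MASS::polr(y ~ snp, data = df, Hess = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(estimate = NA_real_, se = NA_real_,
                            converged = FALSE))
    }
    est <- unname(coef(fit)["snp"])
    se <- sqrt(diag(vcov(fit)))[["snp"]]
    tibble::tibble(estimate = est, se = se, converged = TRUE)
  } else {
    X <- cbind(1, snp = pop$snp[rows])
    res <- linear_block_fit(X, matrix(pop$y[rows], ncol = 1), focal = "snp")
    tibble::tibble(estimate = res$estimate, se = res$se, converged = TRUE)
  }
}

#' Grid of collider-bias simulations
#'
#' For every combination of confounder-on-status odds ratio, variance
#' explained and confounder sign, simulates `n_reps` populations, fits the
#' per-stratum instrument-outcome model (linear for continuous outcomes,
#' proportional-odds for the ordinal kind) in ever and never smokers, and
#' summarizes the estimate distribution and how often the 95% confidence
#' interval includes the null.
#'
#' @param config Base [collider_config()]; its `or_conf_status`,
#'   `r2_conf_outcome` and `conf_sign` are overridden by the grid.
#' @param or_conf_grid Confounder-on-status odds ratios to sweep.
#' @param r2_grid Variance-explained fractions to sweep.
#' @param signs Confounder-effect signs to sweep.
#' @param n_reps Replicates per cell (defaults to `config$n_reps`).
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `collider_bias_grid`, one row per cell and
#'   stratum: mean/SD of estimates, mean SE, fraction of replicates whose CI
#'   includes the null, and the count of non-convergent replicates.
#' @export
run_bias_grid <- function(config = collider_config(),
                          or_conf_grid = c(10, 20, 50, 100),
                          r2_grid = config$r2_conf_outcome,
                          signs = 1, n_reps = NULL, seed = NULL) {
  stopifnot(inherits(config, "collider_sim_config"))
  if (length(or_conf_grid) == 0L) abort("empty grid")
  n_reps <- n_reps %||% config$n_reps
  ordinal <- config$outcome_kind == "ordinal"
  with_seed_if(seed, {
    cells <- expand.grid(or_conf = or_conf_grid, r2 = r2_grid, sign = signs)
    out <- list()
    for (ci in seq_len(nrow(cells))) {
      cfg <- config
      cfg$or_conf_status <- cells$or_conf[ci]
      cfg$r2_conf_outcome <- cells$r2[ci]
      cfg$conf_sign <- cells$sign[ci]
      reps <- list()
      for (r in seq_len(n_reps)) {
        pop <- simulate_collider_population(cfg)
        for (st in c("ever", "never")) {
          fit <- fit_collider_stratum(pop, st, ordinal)
          reps[[length(reps) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(rep = r, stratum = st), fit)
        }
      }
      reps <- dplyr::bind_rows(reps)
      smry <- reps |>
        dplyr::group_by(.data$stratum) |>
        dplyr::summarise(
          n_reps = dplyr::n(),
          n_failed = sum(!.data$converged),
          mean_estimate = mean(.data$estimate, na.rm = TRUE),
          sd_estimate = sd(.data$estimate, na.rm = TRUE),
          mean_se = mean(.data$se, na.rm = TRUE),
          null_in_ci = mean(abs(.data$estimate) < 1.96 * .data$se,
                            na.rm = TRUE),
          .groups = "drop")
      smry$or_conf_status <- cells$or_conf[ci]
      smry$r2_conf_outcome <- cells$r2[ci]
      smry$conf_sign <- cells$sign[ci]
      out[[ci]] <- smry
    }
    res <- dplyr::bind_rows(out)
    res <- res[, c("or_conf_status", "r2_conf_outcome", "conf_sign",
                   "stratum", "n_reps", "n_failed", "mean_estimate",
                   "sd_estimate", "mean_se", "null_in_ci")]
    structure(res, outcome_kind = config$outcome_kind,
              class = c("collider_bias_grid", class(res)))
  })
}

#' False-discovery-rate inflation under collider stratification
#'
#' Simulates a phenome scan of `n_outcomes` null continuous outcomes (no SNP
#' effect on any outcome) that all share the confounder structure of
#' `config`, scans the ever stratum with the linear scan engine, and applies
#' step-up FDR selection at level `alpha`.  Two summaries are returned over
#' the replicates:
#'
#' * `fdr` — the empirical false discovery rate in its standard form, the
#'   mean over replicates of V/R, the proportion of declared hits that are
#'   false (taken as 0 when nothing is declared).  Since every outcome here
#'   is null, V/R is 1 whenever at least one hit is declared, so this equals
#'   the proportion of replicate scans making at least one false discovery.
#' * `prop_flagged` — the mean proportion of the null outcomes declared hits
#'   (a false-positive proportion; almost always far smaller).
#'
#' @param config A [collider_config()] with `snp_outcome_effect = 0` and
#'   continuous outcome kind.
#' @param alpha Step-up FDR level.
#' @param seed Optional integer seed.
#' @param block_size Outcomes simulated per memory block.
#'
#' @return A one-row tibble of class `collider_fdr_sim` with the two
#'   summaries, their Monte-Carlo standard errors, and the simulation sizes;
#'   per-replicate detail is kept in the `"replicates"` attribute.
#' @export
run_fdr_inflation_sim <- function(config = collider_config(), alpha = 0.05,
                                  seed = NULL, block_size = 250L) {
  stopifnot(inherits(config, "collider_sim_config"))
  if (config$snp_outcome_effect != 0) {
    abort("FDR-inflation study requires a null SNP-outcome effect")
  }
  if (config$outcome_kind != "continuous") {
    abort("FDR-inflation study is defined for continuous outcomes")
  }
  if (config$n_outcomes < 100) {
    warn("fewer than 100 outcomes per scan: FDR estimate will be unstable")
  }
  r2 <- config$r2_conf_outcome
  with_seed_if(seed, {
    reps <- vector("list", config$n_reps)
    for (r in seq_len(config$n_reps)) {
      n <- config$n
      g <- rbinom(n, 2L, config$allele_freq)
      u <- rnorm(n)
      offset <- log(config$or_snp_status) * g +
        log(config$or_conf_status) * u
      a <- calibrate_intercept(offset, config$ever_prevalence)
      ever <- rbinom(n, 1L, plogis(a + offset)) == 1L
      ge <- g[ever]
      shared <- config$conf_sign * sqrt(r2) * u[ever]
      ne <- length(ge)
      X <- cbind(`(Intercept)` = 1, snp = ge)
      pvals <- numeric(config$n_outcomes)
      done <- 0L
      while (done < config$n_outcomes) {
        m <- min(block_size, config$n_outcomes - done)
        Y <- rnorm_matrix_affine(ne, m, sqrt(1 - r2), shared)
        pvals[done + seq_len(m)] <- linear_block_fit(X, Y, focal = "snp")$p
        done <- done + m
      }
      sel <- fdr_select(pvals, alpha = alpha, n_tests = config$n_outcomes)
      reps[[r]] <- tibble::tibble(rep = r, n_ever = ne, k = sel$k,
                                  prop_flagged = sel$k / config$n_outcomes,
                                  false_discovery = as.integer(sel$k > 0))
    }
    reps <- dplyr::bind_rows(reps)
    nr <- nrow(reps)
    out <- tibble::tibble(
      or_conf_status = config$or_conf_status,
      r2_conf_outcome = config$r2_conf_outcome,
      n = config$n, n_outcomes = config$n_outcomes, n_reps = nr,
      mean_n_ever = mean(reps$n_ever),
      fdr = mean(reps$false_discovery),
      fdr_mc_se = sd(reps$false_discovery) / sqrt(nr),
      prop_flagged = mean(reps$prop_flagged),
      prop_flagged_mc_se = sd(reps$prop_flagged) / sqrt(nr))
    structure(out, replicates = reps, alpha = alpha,
              class = c("collider_fdr_sim", class(out)))
  })
}
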