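#' Fit the instrument-outcome association for one derived outcome
#'
#' The regression family follows the outcome's data type: linear for
#' continuous (on the inverse-normal-transformed scale, so the estimate is
#' the SD difference per additional effect allele), logistic for binary
#' (log odds of comparison vs baseline), proportional-odds logistic for
#' ordered (log odds of a higher outcome group), and multinomial logistic for
#' unordered.  Scalar estimates carry Wald P values; the multinomial model
#' reports a single whole-model likelihood-ratio chi-square P and no scalar
#' estimate.  Dosage is treated as numeric 0/1/2 (additive allele coding).
#'
#' @param values Outcome vector (numeric for continuous/binary; factor for
#'   categorical types).
#' @param data_type One of `"continuous"`, `"binary"`, `"ordered"`,
#'   `"unordered"`.
#' @param dosage Instrument dosage vector.
#' @param covariates Optional data frame or matrix of numeric covariates.
#'
#' @return One-row tibble: `estimate`, `se`, `p`, `n`, `test`, `converged`.
#' @export
fit_association <- function(values, data_type, dosage, covariates = NULL) {
  stopifnot(data_type %in% data_types)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(values) & !is.na(dosage)
  if (!is.null(C)) keep <- keep & complete.cases(C)
  y <- values[keep]
  g <- dosage[keep]
  C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
  n <- length(y)
  fail <- function(test) tibble::tibble(
    estimate = NA_real_, se = NA_real_, p = NA_real_, n = n, test = test,
    converged = FALSE)

  if (data_type == "continuous") {
    X <- cbind(`(Intercept)` = 1, C, snp = g)
    res <- linear_block_fit(X, matrix(as.numeric(y), ncol = 1), focal = "snp")
    return(tibble::tibble(estimate = res$estimate, se = res$se, p = res$p,
                          n = n, test = "linear", converged = TRUE))
  }

  df <- data.frame(.y = y, .snp = g)
  rhs <- ".snp"
  if (!is.null(C)) {
    cn <- colnames(C) %||% paste0("c", seq_len(ncol(C)))
    colnames(C) <- cn
    df <- cbind(df, as.data.frame(C))
    rhs <- paste(c(cn, ".snp"), collapse = " + ")
  }
  fml <- as.formula(paste(".y ~", rhs))

  if (data_type == "binary") {
    if (!is.factor(df$.y)) df$.y <- factor(df$.y)
    fit <- tryCatch(suppressWarnings(glm(fml, data = df, family = binomial())),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(fail("logistic"))
    sm <- summary(fit)$coefficients
    if (!".snp" %in% rownames(sm)) return(fail("logistic"))
    est <- sm[".snp", 1]; se <- sm[".snp", 2]
    if (!is.finite(se) || se > 50) return(fail("logistic"))
    return(tibble::tibble(estimate = est, se = se,
                          p = 2 * pnorm(-abs(est / se)), n = n,
                          test = "logistic", converged = TRUE))
  }

  if (data_type == "ordered") {
    if (!is.ordered(df$.y)) df$.y <- factor(df$.y, ordered = TRUE)
    df$.y <- droplevels(df$.y)
    fit <- tryCatch(
      suppressWarnings(MASS::polr(fml, data = df, Hess = TRUE,
                                  method = "logistic")),
      error = function(e) NULL)
    if (is.null(fit)) return(fail("ordered logistic"))
    est <- unname(coef(fit)[".snp"])
    se <- tryCatch(sqrt(diag(vcov(fit)))[".snp"], error = function(e) NA_real_)
    if (!is.finite(est) || !is.finite(se) || se > 50) {
      return(fail("ordered logistic"))
    }
    return(tibble::tibble(estimate = est, se = unname(se),
                          p = 2 * pnorm(-abs(est / se)), n = n,
                          test = "ordered logistic", converged = TRUE))
  }

  # unordered: multinomial logistic, whole-model LRT for the dosage term
  if (!is.factor(df$.y)) df$.y <- factor(df$.y)
  df$.y <- droplevels(df$.y)
  fit1 <- tryCatch(nnet::multinom(fml, data = df, trace = FALSE,
                                  maxit = 200),
                   error = function(e) NULL)
  fml0 <- if (is.null(C)) as.formula(".y ~ 1") else {
    as.formula(paste(".y ~", paste(colnames(C), collapse = " + ")))
  }
  fit0 <- tryCatch(nnet::multinom(fml0, data = df, trace = FALSE,
                                  maxit = 200),
                   error = function(e) NULL)
  if (is.null(fit1) || is.null(fit0)) return(fail("multinomial logistic"))
  dev <- fit0$deviance - fit1$deviance
  dfree <- length(levels(df$.y)) - 1L
  tibble::tibble(estimate = NA_real_, se = NA_real_,
                 p = pchisq(max(dev, 0), dfree, lower.tail = FALSE), n = n,
                 test = "multinomial logistic", converged = TRUE)
}

#' Run a phenome scan in one stratum
#'
#' Applies the stratum testability filters and fits the instrument-outcome
#' association for every testable derived outcome within the requested
#' stratum, adjusting for the covariate set.  Continuous outcomes that are
#' fully observed in the stratum share a single QR decomposition of the
#' design, which makes scans over thousands of transformed outcomes cheap;
#' the result is identical to fitting each outcome separately.
#'
#' @param data Participant table (e.g. `$phenotypes` of
#'   [simulate_biobank()]), or a `synthetic_biobank` object.
#' @param outcomes A [derive_outcomes()] tibble aligned to `data`'s rows.
#' @param stratum `"ever"`, `"never"` or `"full"`.
#' @param covariates Character vector of covariate column names; defaults to
#'   age, sex and every `pc<k>` column present.
#' @param instrument Name of the dosage column.
#' @param stratum_var Name of the binary stratifying column.
#' @param min_n,min_per_category Testability filters, see
#'   [apply_stratum_filters()].
#'
#' @return A tibble of class `phewas_scan` with one row per tested outcome
#'   (`outcome_id`, `data_type`, `test`, `estimate`, `se`, `p`, `n`,
#'   `converged`).  Untestable outcomes are recorded in the `"excluded"`
#'   attribute with reasons; the stratum and covariate set are attached as
#'   attributes.
#' @export
run_phenome_scan <- function(data, outcomes,
                             stratum = c("full", "ever", "never"),
                             covariates = NULL, instrument = "snp",
                             stratum_var = "smoking_status",
                             min_n = 500, min_per_category = 10) {
  if (inherits(data, "synthetic_biobank")) data <- data$phenotypes
  stratum <- match.arg(stratum)
  if (is.null(covariates)) {
    covariates <- intersect(c("age", "sex",
                              grep("^pc[0-9]+$", names(data), value = TRUE)),
                            names(data))
  }
  missing_cov <- setdiff(c(instrument, covariates), names(data))
  if (length(missing_cov)) {
    abort(paste0("columns not in data: ", paste(missing_cov, collapse = ", ")))
  }
  mask <- if (stratum == "full") rep(TRUE, nrow(data)) else {
    !is.na(data[[stratum_var]]) & data[[stratum_var]] == stratum
  }
  if (!any(mask)) abort(sprintf("stratum '%s' is empty", stratum))

  filt <- apply_stratum_filters(outcomes, mask, min_n = min_n,
                                min_per_category = min_per_category)
  excluded <- filt[!filt$include, c("outcome_id", "reason")]
  keep <- which(filt$include)

  g <- data[[instrument]][mask]
  C <- if (length(covariates)) {
    as.matrix(data[mask, covariates, drop = FALSE])
  } else NULL
  base_ok <- !is.na(g)
  if (!is.null(C)) base_ok <- base_ok & complete.cases(C)

  rows <- vector("list", length(keep))
  # fast shared-design path: continuous outcomes fully observed on base rows
  is_cont <- outcomes$data_type[keep] == "continuous"
  no_miss <- vapply(outcomes$values[keep], function(v) {
    !anyNA(v[mask][base_ok])
  }, logical(1))
  block <- keep[is_cont & no_miss]
  if (length(block) > 0L) {
    Y <- vapply(outcomes$values[block],
                function(v) as.numeric(v[mask][base_ok]),
                numeric(sum(base_ok)))
    X <- cbind(`(Intercept)` = 1,
               if (is.null(C)) NULL else C[base_ok, , drop = FALSE],
               snp = g[base_ok])
    res <- linear_block_fit(X, Y, focal = "snp")
    for (idx in seq_along(block)) {
      i <- block[idx]
      rows[[match(i, keep)]] <- tibble::tibble(
        outcome_id = outcomes$outcome_id[i], data_type = "continuous",
        test = "linear", estimate = res$estimate[idx], se = res$se[idx],
        p = res$p[idx], n = res$n[1], converged = TRUE)
    }
  }
  slow <- setdiff(keep, block)
  for (i in slow) {
    v <- outcomes$values[[i]][mask]
    v[!base_ok] <- NA
    fit <- fit_association(v, outcomes$data_type[i], g, C)
    rows[[match(i, keep)]] <- dplyr::bind_cols(
      tibble::tibble(outcome_id = outcomes$outcome_id[i],
                     data_type = outcomes$data_type[i]),
      fit[, c("test", "estimate", "se", "p", "n", "converged")])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(outcome_id = character(), data_type = character(),
                          test = character(), estimate = numeric(),
                          se = numeric(), p = numeric(), n = integer(),
                          converged = logical())
  }
  failed <- out[!out$converged, c("outcome_id"), drop = FALSE]
  if (nrow(failed)) {
    excluded <- dplyr::bind_rows(
      excluded, tibble::tibble(outcome_id = failed$outcome_id,
                               reason = "model did not converge"))
    out <- out[out$converged, ]
  }
  structure(out, excluded = excluded, stratum = stratum,
            covariates = covariates,
            class = c("phewas_scan", class(out)))
}

#' Linear phenome scan over an outcome matrix
#'
#' High-throughput companion to [run_phenome_scan()] for simulation studies:
#' regresses every column of `Y` on the instrument dosage (plus optional
#' covariates) over the selected rows, through the same shared-QR ordinary
#' least squares engine the phenome scan uses for continuous outcomes.
#'
#' @param Y Numeric matrix, one column per continuous outcome.
#' @param dosage Instrument dosage vector (length `nrow(Y)`).
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param subset Optional logical vector of rows to scan (e.g. one stratum).
#'
#' @return Tibble with one row per outcome: `estimate`, `se`, `p`, `n`.
#' @export
run_matrix_scan <- function(Y, dosage, covariates = NULL, subset = NULL) {
  Y <- as.matrix(Y)
  stopifnot(length(dosage) == nrow(Y))
  if (!is.null(subset)) {
    Y <- Y[subset, , drop = FALSE]
    dosage <- dosage[subset]
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)[subset, , drop = FALSE]
    }
  }
  X <- cbind(`(Intercept)` = 1,
             if (is.null(covariates)) NULL else as.matrix(covariates),
             snp = dosage)
  linear_block_fit(X, Y, focal = "snp")
}
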