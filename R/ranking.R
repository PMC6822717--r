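#' Cochran's Q heterogeneity test across strata
#'
#' Fixed-effect heterogeneity of per-stratum estimates: with inverse-variance
#' weights \eqn{w_i = 1/se_i^2} and pooled mean
#' \eqn{\bar b = \sum w_i b_i / \sum w_i}, the statistic is
#' \eqn{Q = \sum w_i (b_i - \bar b)^2}, referred to a chi-square distribution
#' with (number of strata - 1) degrees of freedom.  Binary and ordered
#' estimates must be supplied on the log-odds scale (multiplicative
#' interactions).
#'
#' @param estimates Per-stratum effect estimates.
#' @param ses Per-stratum standard errors (all positive).
#'
#' @return A tibble with `Q`, `df` and `p` (upper-tail chi-square).
#' @export
#' @examples
#' cochran_q(c(0.1, -0.1), c(0.05, 0.05))  # Q = 8, p ~ 0.0047
cochran_q <- function(estimates, ses) {
  if (length(estimates) != length(ses)) {
    abort("`estimates` and `ses` must have the same length")
  }
  if (length(estimates) < 2L) abort("need at least 2 strata")
  if (any(!is.finite(ses)) || any(ses <= 0)) abort("all SEs must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - pooled)^2)
  df <- length(estimates) - 1L
  tibble::tibble(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Bonferroni-corrected P value threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests performed.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 16692)  # 3.00e-06
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  check_probability(alpha, "alpha")
  n_tests <- check_count(n_tests, "n_tests")
  alpha / n_tests
}

#' Step-up false-discovery-rate selection
#'
#' Identifies the largest rank position k whose P value is strictly below
#' `alpha * k / n_tests`; the k smallest P values are the hits and
#' `alpha * k / n_tests` is the reported 5% FDR threshold.  Note the strict
#' inequality, which differs from the conventional Benjamini-Hochberg
#' `<=` only when a P value ties the threshold exactly.
#'
#' @param p P values (sorted internally).
#' @param alpha Target false discovery rate.
#' @param n_tests Total number of tests in the ranking; must be at least
#'   `length(p)` (tests without a P value still count towards n).
#'
#' @return A list of class `mr_multiplicity`: `n_tests`, `alpha`,
#'   `bonferroni`, `k`, `threshold` (`NA` when k = 0) and `hits` (the k
#'   smallest P values, ascending).
#' @export
#' @examples
#' fdr_select(c(0.001, 0.2), n_tests = 2)  # k = 1, threshold 0.025
fdr_select <- function(p, alpha = 0.05, n_tests = length(p)) {
  check_probability(alpha, "alpha")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("all P values must lie in (0, 1]")
  }
  n_tests <- check_count(n_tests, "n_tests")
  if (n_tests < length(p)) abort("`n_tests` must be >= length(p)")
  ps <- sort(p)
  below <- which(ps < alpha * seq_along(ps) / n_tests)
  k <- if (length(below)) max(below) else 0L
  structure(
    list(n_tests = n_tests, alpha = alpha,
         bonferroni = alpha / n_tests, k = k,
         threshold = if (k > 0) alpha * k / n_tests else NA_real_,
         hits = ps[seq_len(k)]),
    class = "mr_multiplicity")
}

#' @export
print.mr_multiplicity <- function(x, ...) {
  cat(sprintf("Multiple-testing decision over %d tests (alpha = %g)\n",
              x$n_tests, x$alpha))
  cat(sprintf("  Bonferroni threshold: %s\n", format_p(x$bonferroni)))
  if (x$k > 0) {
    cat(sprintf("  step-up FDR: k = %d hits, threshold %s\n", x$k,
                format_p(x$threshold)))
  } else {
    cat("  step-up FDR: no hits\n")
  }
  invisible(x)
}

#' @method glance mr_multiplicity
#' @export
glance.mr_multiplicity <- function(x, ...) {
  tibble::tibble(n_tests = x$n_tests, alpha = x$alpha,
                 bonferroni = x$bonferroni, k = x$k, threshold = x$threshold)
}

#' Rank outcomes by strength of ever-vs-never interaction
#'
#' Restricts to outcomes with a scalar estimate in both strata under the same
#' test type (multinomial results carry no scalar estimate and are excluded),
#' computes Cochran's Q between the stratum estimates for each, and sorts by
#' ascending interaction P.  The number of interaction tests defines n for
#' multiplicity control.
#'
#' @param ever_scan,never_scan `phewas_scan` tibbles from
#'   [run_phenome_scan()] with identical outcome typing.
#'
#' @return A tibble of class `gxe_ranking`: per-stratum estimates/SEs/Ps/Ns,
#'   `Q`, `df`, `p_interaction` and `rank`, sorted by `p_interaction`.
#' @export
interaction_ranking <- function(ever_scan, never_scan) {
  scalar <- function(s) {
    s <- tibble::as_tibble(s)
    s[!is.na(s$estimate) & !is.na(s$se), ]
  }
  e <- scalar(ever_scan)
  nv <- scalar(never_scan)
  j <- dplyr::inner_join(
    e, nv, by = c("outcome_id", "data_type", "test"),
    suffix = c("_ever", "_never"))
  if (nrow(j) == 0L) {
    abort("no outcome was tested in both strata with the same test type")
  }
  w_e <- 1 / j$se_ever^2
  w_n <- 1 / j$se_never^2
  pooled <- (w_e * j$estimate_ever + w_n * j$estimate_never) / (w_e + w_n)
  Q <- w_e * (j$estimate_ever - pooled)^2 + w_n * (j$estimate_never - pooled)^2
  j$Q <- Q
  j$df <- 1L
  j$p_interaction <- pchisq(Q, 1, lower.tail = FALSE)
  j <- j[order(j$p_interaction), ]
  j$rank <- seq_len(nrow(j))
  structure(j, n_tests = nrow(j),
            class = c("gxe_ranking", class(j)))
}

#' Two-step interaction discovery
#'
#' Step one ranks outcomes by strength of association in the whole sample and
#' keeps the 5% FDR hits; step two ranks those hits by ever-vs-never
#' interaction strength and applies a fresh step-up selection at the reduced
#' number of tests.  The whole-sample association strength is independent of
#' the between-stratum interaction, which is what makes the two-step
#' procedure valid.
#'
#' @param full_scan,ever_scan,never_scan `phewas_scan` tibbles sharing
#'   outcome typing.
#' @param alpha Target FDR at both steps.
#'
#' @return A list of class `gxe_two_step`: `step1` (an `mr_multiplicity`),
#'   `table` (interaction ranking restricted to step-1 hits possessing an
#'   interaction P), and `step2` (`mr_multiplicity` at the reduced n), or an
#'   empty result when step 1 selects nothing.
#' @export
two_step_interaction <- function(full_scan, ever_scan, never_scan,
                                 alpha = 0.05) {
  fs <- tibble::as_tibble(full_scan)
  fs <- fs[!is.na(fs$p), ]
  step1 <- fdr_select(fs$p, alpha = alpha, n_tests = nrow(fs))
  fs <- fs[order(fs$p), ]
  hit_ids <- fs$outcome_id[seq_len(step1$k)]
  if (step1$k == 0L) {
    return(structure(list(step1 = step1, table = NULL, step2 = NULL),
                     class = "gxe_two_step"))
  }
  ranking <- interaction_ranking(ever_scan, never_scan)
  ranking <- ranking[ranking$outcome_id %in% hit_ids, ]
  if (nrow(ranking) == 0L) {
    return(structure(list(step1 = step1, table = NULL, step2 = NULL),
                     class = "gxe_two_step"))
  }
  ranking$rank <- seq_len(nrow(ranking))
  step2 <- fdr_select(ranking$p_interaction, alpha = alpha,
                      n_tests = nrow(ranking))
  structure(list(step1 = step1, table = ranking, step2 = step2),
            class = "gxe_two_step")
}

#' QQ-plot data for a set of P values
#'
#' Pairs observed P values with uniform order-statistic expectations
#' `(i - 0.5) / m` on the -log10 scale, and attaches the Bonferroni and 5%
#' FDR reference thresholds for the set.
#'
#' @param p P values in (0, 1].
#' @param alpha Significance level for the attached thresholds.
#'
#' @return A tibble of class `gxe_qq` with `expected` and `observed`
#'   (-log10), plus `bonferroni` and `fdr_threshold` attributes.
#' @export
qq_data <- function(p, alpha = 0.05) {
  if (length(p) == 0L) abort("no P values supplied")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("all P values must lie in (0, 1]")
  }
  m <- length(p)
  ps <- sort(p)
  sel <- fdr_select(ps, alpha = alpha, n_tests = m)
  out <- tibble::tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(ps))
  structure(out, bonferroni = alpha / m, fdr_threshold = sel$threshold,
            class = c("gxe_qq", class(out)))
}
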