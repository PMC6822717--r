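#' QQ plot of phenome-scan P values
#'
#' @param object A `gxe_qq` tibble from [qq_data()].
#' @param ... Unused.
#' @return A ggplot object: observed vs expected -log10 P with the identity
#'   line and the Bonferroni / 5% FDR reference thresholds.
#' @method autoplot gxe_qq
#' @export
autoplot.gxe_qq <- function(object, ...) {
  bon <- attr(object, "bonferroni")
  fdr <- attr(object, "fdr_threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$expected,
                                            y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "blue") +
    ggplot2::geom_point(colour = "purple", size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(bon), linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::labs(x = expression(Expected ~ -log[10](P)),
                  y = expression(Observed ~ -log[10](P)))
  if (!is.na(fdr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(fdr),
                                 linetype = "dotdash", colour = "red")
  }
  p
}

#' @rdname autoplot.gxe_qq
#' @method autoplot phewas_scan
#' @export
autoplot.phewas_scan <- function(object, ...) {
  autoplot(qq_data(object$p[!is.na(object$p)]))
}

#' @rdname autoplot.gxe_qq
#' @method autoplot gxe_ranking
#' @export
autoplot.gxe_ranking <- function(object, ...) {
  autoplot(qq_data(object$p_interaction))
}

#' Plot a collider-bias simulation grid
#'
#' @param object A `collider_bias_grid` from [run_bias_grid()].
#' @param ... Unused.
#' @return A ggplot: mean per-stratum estimate with +/- 1.96 mean SE bars for
#'   every grid cell.
#' @method autoplot collider_bias_grid
#' @export
autoplot.collider_bias_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$or_conf_status),
                               y = .data$mean_estimate,
                               colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_estimate - 1.96 * .data$mean_se,
                   ymax = .data$mean_estimate + 1.96 * .data$mean_se),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(.data$conf_sign ~ .data$r2_conf_outcome,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "confounder odds ratio on stratum membership",
                  y = "instrument-outcome estimate")
}

#' @method glance phewas_scan
#' @export
glance.phewas_scan <- function(x, ...) {
  tibble::tibble(
    stratum = attr(x, "stratum"),
    n_tested = nrow(x),
    n_excluded = nrow(attr(x, "excluded")),
    min_p = if (nrow(x)) min(x$p, na.rm = TRUE) else NA_real_)
}

#' @method glance gxe_ranking
#' @export
glance.gxe_ranking <- function(x, ...) {
  sel <- fdr_select(x$p_interaction, n_tests = attr(x, "n_tests"))
  tibble::tibble(n_tests = attr(x, "n_tests"),
                 bonferroni = sel$bonferroni,
                 fdr_k = sel$k, fdr_threshold = sel$threshold)
}

#' @method tidy gxe_two_step
#' @export
tidy.gxe_two_step <- function(x, ...) {
  if (is.null(x$table)) return(tibble::tibble())
  tibble::as_tibble(x$table)
}

#' @method glance gxe_two_step
#' @export
glance.gxe_two_step <- function(x, ...) {
  tibble::tibble(
    step1_k = x$step1$k,
    step1_threshold = x$step1$threshold,
    step2_n = if (is.null(x$table)) 0L else nrow(x$table),
    step2_k = if (is.null(x$step2)) 0L else x$step2$k,
    step2_threshold = if (is.null(x$step2)) NA_real_ else x$step2$threshold)
}
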