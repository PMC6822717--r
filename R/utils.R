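# internal helpers shared across modules

# Run `expr` under a temporarily-seeded RNG when `seed` is given; leave the
# caller's RNG stream untouched in that case.  With seed = NULL the global
# stream is used (and advanced) as usual.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

# Deterministic child seed for the C++ generator: drawn from the R stream so
# that set.seed()/seed arguments govern it like any other draw.
child_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

# Fast standard-normal matrix (xoshiro256++ / ziggurat, see src/).
rnorm_matrix <- function(n, m, seed = NULL) {
  if (is.null(seed)) seed <- child_seed()
  .rnorm_matrix_cpp(as.integer(n), as.integer(m), as.numeric(seed))
}

# offset + scale * Z without intermediate allocations
rnorm_matrix_affine <- function(n, m, scale, offset, seed = NULL) {
  if (is.null(seed)) seed <- child_seed()
  .rnorm_matrix_affine_cpp(as.integer(n), as.integer(m), as.numeric(seed),
                           as.numeric(scale), as.numeric(offset))
}

check_probability <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single probability in %s",
                  name, if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Intercept calibration by bisection: find a such that
# mean(plogis(a + offset)) == target, to within `tol` on the prevalence.
calibrate_intercept <- function(offset, target, tol = 1e-6, max_iter = 200L) {
  f <- function(a) mean(plogis(a + offset)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    abort("prevalence calibration failed: target unreachable")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Ordinary least squares for a shared design and many response columns.
# Returns the coefficient, standard error and two-sided t-test P for one
# focal column of X, for every column of Y.  Identical (to numerical
# precision) to looping lm() over the columns.
linear_block_fit <- function(X, Y, focal) {
  n <- nrow(X)
  p <- ncol(X)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  # exact collinearity can survive chol() at rounding level: require every
  # pivot to carry a non-negligible share of its column's scale
  if (!is.null(R) && any(diag(R)^2 < 1e-10 * diag(XtX))) R <- NULL
  if (is.null(R)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    abort(paste0("rank-deficient design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  XtX_inv <- chol2inv(R)
  XtY <- crossprod(X, Y)
  B <- XtX_inv %*% XtY
  rss <- .col_sumsq_cpp(as.matrix(Y)) - colSums(B * XtY)
  rss <- pmax(rss, 0)
  df <- n - p
  sigma2 <- rss / df
  j <- if (is.character(focal)) match(focal, colnames(X)) else focal
  est <- B[j, ]
  se <- sqrt(sigma2 * XtX_inv[j, j])
  tval <- est / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tibble::tibble(estimate = unname(est), se = unname(se), p = unname(pval),
                 n = n)
}

# significant-digit scientific formatting used in result tables ("3.00e-06")
format_p <- function(p, digits = 3) {
  ifelse(is.na(p), NA_character_, formatC(p, format = "e", digits = digits - 1))
}
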