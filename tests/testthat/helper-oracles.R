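# Independent brute-force oracles used to cross-check the model-fitting and
# selection code.  These deliberately avoid glm()/polr()/multinom() and the
# package's own fdr_select(): likelihoods are written out and maximized
# numerically, and the step-up rule is enumerated rank by rank.

# step-up FDR by exhaustive enumeration of every rank
brute_force_fdr_k <- function(p, alpha = 0.05, n_tests = length(p)) {
  ps <- sort(p)
  k <- 0L
  for (r in seq_along(ps)) {
    if (ps[r] < alpha * r / n_tests) k <- r
  }
  k
}

# logistic regression by direct likelihood maximization
oracle_logistic <- function(y, X) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# proportional-odds logistic regression (y integer 1..K) by direct likelihood
# maximization over (thresholds as increments, beta)
oracle_polr <- function(y, X, K = max(y)) {
  nll <- function(par) {
    zeta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
    beta <- par[K:(length(par))]
    eta <- drop(X %*% beta)
    pU <- ifelse(y == K, 1, plogis(zeta[pmin(y, K - 1)] - eta))
    pL <- ifelse(y == 1, 0, plogis(zeta[pmax(y - 1, 1)] - eta))
    -sum(log(pmax(pU - pL, 1e-300)))
  }
  init <- c(qlogis(cumsum(table(y) / length(y))[1]),
            rep(0, K - 2), rep(0, ncol(X)))
  fit <- optim(init, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(beta = fit$par[K:length(fit$par)],
       zeta = cumsum(c(fit$par[1], exp(fit$par[2:(K - 1)]))))
}

# multinomial logistic deviance at the maximum, by direct maximization
oracle_multinom_deviance <- function(y, X) {
  K <- length(unique(y))
  y <- as.integer(factor(y))
  p <- ncol(X)
  nll <- function(par) {
    B <- matrix(par, nrow = p, ncol = K - 1)
    eta <- cbind(0, X %*% B)
    denom <- log(rowSums(exp(eta)))
    -sum(eta[cbind(seq_along(y), y)] - denom)
  }
  fit <- optim(rep(0, p * (K - 1)), nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  2 * fit$value
}

# Frisch-Waugh partialled-out OLS coefficient for the focal column
oracle_fw_coefficient <- function(y, focal, covars) {
  Xc <- cbind(1, covars)
  rf <- focal - Xc %*% solve(crossprod(Xc), crossprod(Xc, focal))
  ry <- y - Xc %*% solve(crossprod(Xc), crossprod(Xc, y))
  sum(rf * ry) / sum(rf^2)
}
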