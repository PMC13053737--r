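# Independent oracles.  These deliberately avoid the package's fitting path:
# the mixed-model likelihood is assembled as ONE dense covariance matrix over
# all observations and maximized by a generic derivative-free optimizer.

# dense two-level random-intercept Gaussian log-likelihood
# V = tau_p^2 Zp Zp' + tau_i^2 Zi Zi' + sigma^2 I, beta profiled out by GLS
dense_intercept_loglik <- function(logpar, y, X, pair, person) {
  tau_p2 <- exp(2 * logpar[1]); tau_i2 <- exp(2 * logpar[2])
  sig2 <- exp(2 * logpar[3])
  Zp <- outer(pair, unique(pair), "==") * 1
  Zi <- outer(person, unique(person), "==") * 1
  V <- tau_p2 * tcrossprod(Zp) + tau_i2 * tcrossprod(Zi) +
    diag(sig2, length(y))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(r * Vi_r))
}

# brute-force ML: multi-start Nelder-Mead over the three log-SDs
brute_force_ml <- function(y, X, pair, person) {
  starts <- list(log(c(1, 1, 1)), log(c(3, 3, 3)), log(c(0.3, 2, 1)),
                 log(c(2, 0.3, 2)))
  best <- -Inf
  for (s in starts) {
    opt <- optim(s, function(p)
      -dense_intercept_loglik(p, y, X, pair, person),
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-13))
    if (-opt$value > best) best <- -opt$value
  }
  best
}

# dense log-likelihood of a fitted lgcm at its own parameter estimates,
# for arbitrary random structure: rebuilds V from VarCorr blocks
dense_loglik_at_fit <- function(fit) {
  m <- fit$fit
  d <- m@frame
  y <- d$y
  X <- lme4::getME(m, "X")
  beta <- lme4::fixef(m)
  vc <- lme4::VarCorr(m)
  n <- length(y)
  V <- diag(stats::sigma(m)^2, n)
  for (grp in names(vc)) {
    G <- as.matrix(vc[[grp]])
    cols <- rownames(G)
    Zcols <- sapply(cols, function(cn)
      if (cn == "(Intercept)") rep(1, n) else d[[cn]])
    Zcols <- matrix(Zcols, nrow = n)
    g <- as.character(d[[grp]])
    for (lev in unique(g)) {
      idx <- which(g == lev)
      Zi <- Zcols[idx, , drop = FALSE]
      V[idx, idx] <- V[idx, idx] + Zi %*% G %*% t(Zi)
    }
  }
  r <- y - X %*% beta
  ch <- chol(V)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r * Vi_r))
}

# within- and between-pair OLS coefficients from per-person values
ols_between_within <- function(x, y, pair_id) {
  pm_x <- tapply(x, pair_id, mean)[as.character(pair_id)]
  pm_y <- tapply(y, pair_id, mean)[as.character(pair_id)]
  fb <- summary(lm(unique_pairs(pm_y, pair_id) ~
                     unique_pairs(pm_x, pair_id)))$coefficients
  fw <- summary(lm(I(y - pm_y) ~ 0 + I(x - pm_x)))$coefficients
  list(between = fb[2, 1], between_se = fb[2, 2],
       within = fw[1, 1], within_se = fw[1, 2])
}

unique_pairs <- function(v, pair_id) as.numeric(v[!duplicated(pair_id)])
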