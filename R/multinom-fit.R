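# Core penalised maximum-likelihood fits used by both the association scan
# and the blood-type classifier. Written as plain Newton/IRLS so the
# separation contract (fixed tiny ridge + convergence flag) is explicit.

# Logistic regression by IRLS with an optional ridge on non-intercept
# coefficients. Returns coefficients, covariance, convergence flag.
fit_logistic_core <- function(X, y, ridge = 0, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    hess <- crossprod(X * w, X) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (max(abs(beta)) > 1e4) break  # runaway: separation without ridge
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-12)
  hess <- crossprod(X * w, X) + pen
  vcov <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, p, p))
  mu_c <- pmin(pmax(mu, 1e-300), 1 - 1e-16)
  loglik <- sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
  list(coef = beta, vcov = vcov, converged = converged, loglik = loglik)
}

# Detects (quasi-)separation from an unpenalised fit: diverging
# coefficients or exploding standard errors.
looks_separated <- function(fit) {
  !fit$converged || max(abs(fit$coef)) > 15 ||
    anyNA(diag(fit$vcov)) || max(sqrt(diag(fit$vcov))) > 100
}

# Multinomial log-linear model, reference level first:
# log(P(k)/P(ref)) = X %*% beta_k for k = 2..K. Fitted by Newton with
# step-halving; ridge penalises non-intercept coefficients of every class.
# fix_idx: indices of vec(beta) (column-major over classes 2..K)
# constrained to zero, for likelihood-ratio fallbacks under separation.
# Returns a (p x (K-1)) coefficient matrix, vcov of vec(beta), flags.
fit_multinom_core <- function(X, y, ridge = 0, max_iter = 200, tol = 1e-9,
                              fix_idx = integer(0)) {
  stopifnot(is.factor(y))
  K <- nlevels(y)
  if (K < 2) stop_abokit("outcome has fewer than 2 levels")
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  nc <- K - 1
  beta <- matrix(0, p, nc)  # columns: levels 2..K vs level 1
  pen_diag <- rep(c(0, rep(ridge, p - 1)), nc)
  pen <- diag(pen_diag, p * nc)

  probs_of <- function(beta) {
    eta <- cbind(0, X %*% beta)
    eta <- eta - apply(eta, 1, max)
    e <- exp(eta)
    e / rowSums(e)
  }
  pen_loglik <- function(beta) {
    pr <- probs_of(beta)
    sum(Y * log(pmax(pr, 1e-300))) - 0.5 * sum(pen_diag * as.vector(beta)^2)
  }

  converged <- FALSE
  ll <- pen_loglik(beta)
  for (iter in seq_len(max_iter)) {
    pr <- probs_of(beta)
    # gradient: X'(Y_k - pr_k) per non-reference class, minus penalty
    grad <- as.vector(crossprod(X, Y[, -1, drop = FALSE] - pr[, -1, drop = FALSE])) -
      pen_diag * as.vector(beta)
    # Hessian blocks: -X' diag(pr_k (delta_kl - pr_l)) X
    H <- matrix(0, p * nc, p * nc)
    for (a in seq_len(nc)) {
      for (b in a:nc) {
        w <- if (a == b) pr[, a + 1] * (1 - pr[, a + 1]) else -pr[, a + 1] * pr[, b + 1]
        blk <- crossprod(X * w, X)
        ra <- (a - 1) * p + seq_len(p); rb <- (b - 1) * p + seq_len(p)
        H[ra, rb] <- blk
        if (a != b) H[rb, ra] <- blk
      }
    }
    H <- H + pen
    free <- setdiff(seq_len(p * nc), fix_idx)
    step <- rep(0, p * nc)
    step_free <- tryCatch(solve(H[free, free, drop = FALSE], grad[free]),
                          error = function(e) NULL)
    if (is.null(step_free)) break
    step[free] <- step_free
    # step-halving line search on the penalised log-likelihood
    lambda <- 1
    repeat {
      beta_new <- beta + matrix(lambda * step, p, nc)
      ll_new <- pen_loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- pen_loglik(beta)
    if (moved < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
    if (max(abs(beta)) > 1e4) break
  }
  pr <- probs_of(beta)
  H <- matrix(0, p * nc, p * nc)
  for (a in seq_len(nc)) {
    for (b in a:nc) {
      w <- if (a == b) pmax(pr[, a + 1] * (1 - pr[, a + 1]), 1e-12)
           else -pr[, a + 1] * pr[, b + 1]
      blk <- crossprod(X * w, X)
      ra <- (a - 1) * p + seq_len(p); rb <- (b - 1) * p + seq_len(p)
      H[ra, rb] <- blk
      if (a != b) H[rb, ra] <- blk
    }
  }
  H <- H + pen
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p * nc, p * nc))
  dimnames(beta) <- list(colnames(X), levels(y)[-1])
  loglik_unpen <- sum(Y * log(pmax(probs_of(beta), 1e-300)))
  list(coef = beta, vcov = vcov, converged = converged, loglik = ll,
       loglik_unpen = loglik_unpen, levels = levels(y))
}

# Separation heuristic for the multinomial fit.
multinom_looks_separated <- function(fit) {
  !fit$converged || max(abs(fit$coef)) > 15 ||
    anyNA(diag(fit$vcov)) || max(sqrt(pmax(diag(fit$vcov), 0))) > 100
}
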