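# Independent solver oracles used to cross-check the package's
# implementations on small instances.

# ADMM for min ||Mf - u||^2 + l1 |f|_1 + l2 ||f||^2 (split f = z).
admm_en <- function(M, u, l1, l2 = 0, rho = 2, iters = 10000, tol = 1e-13) {
  n <- ncol(M)
  A <- 2 * crossprod(M) + diag(2 * l2 + rho, n)
  R <- chol(A)
  Mu2 <- 2 * crossprod(M, u)
  z <- w <- numeric(n)
  for (i in seq_len(iters)) {
    f <- backsolve(R, forwardsolve(t(R), Mu2 + rho * (z - w)))[, 1]
    v <- f + w
    z_new <- sign(v) * pmax(abs(v) - l1 / rho, 0)
    w <- w + f - z_new
    if (max(abs(z_new - z)) < tol && max(abs(f - z_new)) < tol) {
      z <- z_new
      break
    }
    z <- z_new
  }
  z
}

en_objective <- function(M, u, f, l1, l2 = 0) {
  sum((M %*% f - u)^2) + l1 * sum(abs(f)) + l2 * sum(f^2)
}

# Brute-force Gaussian marginal likelihood of the linear model
# u ~ N(M f, I/beta), f ~ N(0, I/alpha), via the exact covariance.
marginal_loglik <- function(M, u, alpha, beta) {
  m2 <- nrow(M)
  C <- diag(m2) / beta + tcrossprod(M) / alpha
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  drop(-0.5 * t(u) %*% solve(C, u) - 0.5 * ld - (m2 / 2) * log(2 * pi))
}

# Leave-one-out squared prediction error of ridge at penalty lambda.
loo_ridge <- function(M, u, lambda) {
  errs <- vapply(seq_len(nrow(M)), function(i) {
    Mi <- M[-i, , drop = FALSE]
    ui <- u[-i]
    f <- solve(crossprod(Mi) + diag(lambda, ncol(M)), crossprod(Mi, ui))
    (u[i] - drop(M[i, , drop = FALSE] %*% f))^2
  }, numeric(1))
  mean(errs)
}

default_substrate <- function() elastic_substrate(10e3, 0.3)
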