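test_that("standardization matches the printed definitions", {
  # hand 3 x 2 matrix: spreads are sample standard deviations (2m - 1)
  M <- matrix(c(1, 2, 6, -1, 0, 4), 3, 2)
  u <- c(0.5, -1, 2)
  pr <- standardize_problem(M, u)
  expect_equal(pr$column_spreads, c(sd(M[, 1]), sd(M[, 2])))
  expect_equal(pr$column_means, colMeans(M))
  expect_equal(pr$u_mean, mean(u))
  expect_equal(colMeans(pr$Mt), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(pr$Mt, 2, sd), c(1, 1), tolerance = 1e-10)
  expect_equal(mean(pr$ut), 0, tolerance = 1e-12)

  # idempotence: standardizing a standardized problem changes nothing
  pr2 <- standardize_problem(pr$Mt, pr$ut)
  expect_equal(pr2$Mt, pr$Mt, tolerance = 1e-12)
  expect_equal(pr2$ut, pr$ut, tolerance = 1e-12)

  # zero-spread column reported by index
  Mbad <- cbind(M[, 1], 3)
  expect_error(standardize_problem(Mbad, u), "column\\(s\\) in M: 2")
})

test_that("MAP traction is the de-standardized ridge solution", {
  set.seed(21)
  M <- matrix(rnorm(20 * 8), 20, 8)
  u <- rnorm(20)
  pr <- standardize_problem(M, u)
  alpha <- 3; beta <- 7
  f <- map_traction(pr, alpha, beta)
  ridge <- solve_l2(pr$Mt, pr$ut, alpha / beta)$traction
  expect_equal(f, ridge / pr$column_spreads, tolerance = 1e-10,
               ignore_attr = TRUE)

  # only the ratio alpha / beta matters
  f2 <- map_traction(pr, 30, 70)
  expect_equal(unname(f2), unname(f), tolerance = 1e-10)

  # strong prior shrinks everything away
  f3 <- map_traction(pr, 1e12, 1)
  expect_lt(max(abs(f3)), 1e-8)
})

test_that("log evidence equals the exact Gaussian marginal likelihood", {
  set.seed(22)
  # property-based over several small shapes, incl. 1-D (m = n = 1)
  shapes <- list(c(2, 2), c(2, 4), c(6, 4), c(10, 8))
  for (sh in shapes) {
    M <- matrix(rnorm(sh[1] * sh[2]), sh[1], sh[2])
    u <- rnorm(sh[1])
    pr <- standardize_problem(M, u, center_scale = FALSE)
    for (ab in list(c(1, 1), c(0.3, 5), c(40, 0.7))) {
      lev <- log_evidence(pr, ab[1], ab[2])
      expect_equal(lev, marginal_loglik(M, u, ab[1], ab[2]),
                   tolerance = 1e-8)
      # eigen engine route agrees with the Cholesky route
      en <- evidence_engine(pr)
      expect_equal(log_evidence(pr, ab[1], ab[2], engine = en), lev,
                   tolerance = 1e-8)
    }
  }

  # direct numerical integration over f for a 1-D toy
  M1 <- matrix(0.8, 1, 1)
  u1 <- 0.4
  pr1 <- standardize_problem(M1, u1, center_scale = FALSE)
  alpha <- 2.3; beta <- 1.7
  f_grid <- seq(-10, 10, length.out = 20001)
  integrand <- exp(-beta * (M1[1] * f_grid - u1)^2 / 2 -
                     alpha * f_grid^2 / 2)
  Z <- sum(integrand) * diff(f_grid)[1] *
    sqrt(beta / (2 * pi)) * sqrt(alpha / (2 * pi))
  expect_equal(log_evidence(pr1, alpha, beta), log(Z), tolerance = 1e-8)

  # M = 0 limit: f integrates out, leaving the pure-noise likelihood
  pr0 <- standardize_problem(matrix(0, 4, 2), rnorm(4),
                             center_scale = FALSE)
  lev0 <- log_evidence(pr0, 1.3, 2.1)
  expect_equal(lev0, sum(dnorm(pr0$ut, 0, 1 / sqrt(2.1), log = TRUE)),
               tolerance = 1e-10)
})

test_that("Cholesky log-determinant matches the dense determinant", {
  set.seed(23)
  B <- matrix(rnorm(400), 20, 20)
  A <- crossprod(B) + diag(0.5, 20)
  ld_chol <- 2 * sum(log(diag(chol(A))))
  ld_dense <- determinant(A, logarithm = TRUE)$modulus
  expect_equal(ld_chol, as.numeric(ld_dense), tolerance = 1e-9)
})

test_that("background noise estimation recovers known sigma", {
  set.seed(24)
  bg <- data.frame(x = 0, y = 0,
                   ux = rnorm(1e4, 0, 0.05), uy = rnorm(1e4, 0, 0.05))
  beta_hat <- estimate_beta_background(bg)
  expect_equal(beta_hat, 400, tolerance = 0.05)

  # constant drift is removed by mean subtraction
  bg2 <- bg
  bg2$ux <- bg2$ux + 3
  expect_equal(estimate_beta_background(bg2), beta_hat, tolerance = 1e-10)

  expect_error(estimate_beta_background(bg[1:5, ]), "at least 10")
})

test_that("BL2 recovers the generating prior precision", {
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    n2 <- 200; m2 <- 300; a0 <- 4; b0 <- 100
    M <- matrix(rnorm(m2 * n2), m2, n2)
    f <- rnorm(n2, 0, 1 / sqrt(a0))
    u <- drop(M %*% f) + rnorm(m2, 0, 1 / sqrt(b0))
    r <- bl2(M, u, beta = b0)
    r$alpha / a0
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("BL2 evidence curve is unimodal on protocol-style data", {
  dat <- desk_scale_data(seed = 2, noise_percent = 5, m = 400L)
  beta <- 1 / dat$sigma^2
  r <- bl2(dat$op, dat$field, beta = beta)
  lev <- r$surface$log_evidence
  grad_sign <- sign(diff(lev))
  # single sign change of the discrete gradient: rises then falls
  changes <- sum(diff(grad_sign[grad_sign != 0]) != 0)
  expect_equal(changes, 1)
  expect_false(r$boundary)

  # ridge invariance: scaling u and M by c and beta by 1/c^2 describes
  # the same physical data, and after standardization (columns of M are
  # scale-free, f_std absorbs c which cancels against beta) the selected
  # lambda and the physical MAP traction are unchanged
  op2 <- dat$op
  op2$matrix <- op2$matrix * 3
  u2 <- as.data.frame(dat$field)
  u2[c("ux", "uy")] <- u2[c("ux", "uy")] * 3
  r2 <- bl2(op2$matrix, as.vector(rbind(u2$ux, u2$uy)), beta = beta / 9)
  expect_equal(r2$lambda, r$lambda, tolerance = 0.01)
  expect_equal(r2$f_map, r$f_map, tolerance = 0.01)
})

test_that("ABL2 grid scan and fixed-point refinement coincide", {
  set.seed(26)
  n2 <- 8; m2 <- 10
  M <- matrix(rnorm(m2 * n2), m2, n2)
  f <- rnorm(n2, 0, 0.5)
  u <- drop(M %*% f) + rnorm(m2, 0, 0.1)
  r_grid <- abl2(M, u, method = "grid")
  r_fp <- abl2(M, u, method = "fixed_point")
  expect_equal(r_fp$alpha, r_grid$alpha, tolerance = 0.01)
  expect_equal(r_fp$beta, r_grid$beta, tolerance = 0.01)
  # the reported maximum dominates every sampled surface point
  expect_gte(r_grid$log_evidence + 1e-8,
             max(r_grid$surface$log_evidence))
  expect_equal(r_grid$lambda, r_grid$alpha / r_grid$beta)
})

test_that("glance and tidy expose evidence results tidily", {
  set.seed(27)
  M <- matrix(rnorm(60), 10, 6)
  u <- rnorm(10)
  r <- bl2(M, u, beta = 50)
  g <- glance(r)
  expect_named(g, c("method", "alpha", "beta", "lambda", "log_evidence",
                    "boundary"))
  expect_equal(g$lambda, r$alpha / 50)
  expect_s3_class(tidy(r), "tbl_df")
})
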