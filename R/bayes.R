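#' @title Evidence-based automatic L2 regularization
#' @description With a Gaussian prior `p(f | alpha) ~ exp(-alpha f'f / 2)`
#'   and Gaussian likelihood `p(u | f, beta) ~ exp(-beta ||Mf - u||^2 / 2)`,
#'   the posterior maximizer coincides with Tikhonov regularization at
#'   `lambda = alpha / beta`, and the marginal likelihood (evidence) of the
#'   data is available in closed form. [bl2()] fixes beta from measured
#'   background noise and maximizes the log evidence over alpha; [abl2()]
#'   maximizes jointly over `(alpha, beta)`. Both operate on the
#'   standardized problem (centred displacement, columns of M scaled to
#'   unit spread).
#' @name bayes
NULL

#' Standardize a traction inverse problem
#'
#' Centres the displacement vector (`u - mean(u)`), and centres and scales
#' every column of M to unit sample standard deviation (denominator
#' `2m - 1`). The returned object records everything needed to
#' de-standardize a solution (`f = f_std / omega`).
#'
#' @param M A [forward_operator] or numeric matrix (2m x 2n).
#' @param u A [displacement_field()] or interleaved numeric vector.
#' @param center_scale Set `FALSE` to wrap an already-standardized problem
#'   unchanged (identity scaling).
#' @param materialize Set `FALSE` to keep only the raw matrix plus the
#'   column statistics; the standardized matrix is then formed lazily on
#'   first use. The evidence machinery never needs it explicitly (it works
#'   from `M'M` with rank-one centering corrections), which saves two
#'   full-size matrix copies on large problems.
#' @return A `tfm_standardized` list with elements `Mt`, `ut`,
#'   `column_means`, `column_spreads`, `u_mean`, `n`, `m`, `grid`.
#' @export
standardize_problem <- function(M, u, center_scale = TRUE,
                                materialize = TRUE) {
  check_units(M, u)
  grid <- if (is_forward_operator(M)) M$grid else NULL
  Mm <- operator_matrix(M)
  uv <- as_displacement_vector(u)
  if (center_scale && nrow(Mm) < 2) {
    stop("Need at least two displacement components.", call. = FALSE)
  }
  if (length(uv) != nrow(Mm)) {
    stop("Dimension mismatch between operator and displacements.",
         call. = FALSE)
  }
  if (center_scale) {
    ubar <- mean(uv)
    ut <- uv - ubar
    mbar <- colMeans(Mm)
    omega <- sqrt((colSums(Mm^2) - nrow(Mm) * mbar^2) / (nrow(Mm) - 1))
    bad <- which(omega <= 0 | !is.finite(omega))
    if (length(bad) > 0) {
      stop("Zero-spread column(s) in M: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    Mt <- if (materialize) {
      sweep(sweep(Mm, 2, mbar), 2, omega, `/`)
    } else {
      NULL
    }
  } else {
    ubar <- 0
    ut <- uv
    mbar <- rep(0, ncol(Mm))
    omega <- rep(1, ncol(Mm))
    Mt <- if (materialize) Mm else NULL
  }
  structure(list(Mt = Mt, M_raw = if (is.null(Mt)) Mm else NULL, ut = ut,
                 column_means = mbar, column_spreads = omega,
                 u_mean = ubar,
                 n = ncol(Mm) / 2, m = nrow(Mm) / 2, grid = grid),
            class = "tfm_standardized")
}

is_standardized <- function(x) inherits(x, "tfm_standardized")

# Standardized matrix, built on demand for lazily standardized problems.
problem_matrix <- function(problem) {
  if (!is.null(problem$Mt)) return(problem$Mt)
  sweep(sweep(problem$M_raw, 2, problem$column_means),
        2, problem$column_spreads, `/`)
}

# Crossproduct t(Ms) %*% Ms and projection t(Ms) %*% ut of the
# standardized problem, using rank-one centering corrections so the
# standardized matrix itself is never formed on the lazy path.
problem_gram <- function(problem) {
  if (!is.null(problem$Mt)) {
    list(G = crossprod(problem$Mt), b0 = crossprod(problem$Mt, problem$ut))
  } else {
    Mm <- problem$M_raw
    mbar <- problem$column_means
    om <- problem$column_spreads
    G <- crossprod(Mm) - nrow(Mm) * tcrossprod(mbar)
    G <- G / tcrossprod(om)
    # 1' ut = 0 after centering, so the mean term drops out of b0
    b0 <- crossprod(Mm, problem$ut) / om
    list(G = G, b0 = b0)
  }
}

#' Maximum-posterior traction at fixed hyperparameters
#'
#' Ridge solution of the standardized problem at `lambda = alpha / beta`,
#' de-standardized back to physical units (Pa). Only the ratio of the two
#' hyperparameters enters.
#'
#' @param problem A [standardize_problem()] result.
#' @param alpha Prior inverse variance (> 0).
#' @param beta Noise inverse variance (> 0).
#' @return De-standardized traction vector; the standardized solution is
#'   attached as attribute `f_std`.
#' @export
map_traction <- function(problem, alpha, beta) {
  stopifnot(is_standardized(problem), alpha > 0, beta > 0)
  f_std <- ridge_solve(problem_matrix(problem), problem$ut, alpha / beta)
  f <- f_std / problem$column_spreads
  attr(f, "f_std") <- f_std
  f
}

#' Log evidence of the standardized problem
#'
#' The closed-form log marginal likelihood
#' \deqn{\log p(u\mid\alpha,\beta) = -\alpha E_f - \beta E_u
#'   - \tfrac12\log\det A + n\log\alpha + m\log\beta - m\log 2\pi,}
#' with `E_f = f'f/2` and `E_u = ||Mf - u||^2/2` evaluated at the posterior
#' maximizer, `A = alpha I + beta M'M` the posterior Hessian, and `n`, `m`
#' the node and sample counts (half the stacked dimensions). The
#' log-determinant is taken from a Cholesky factorization, or from a
#' precomputed [evidence_engine()] when supplied.
#'
#' @inheritParams map_traction
#' @param engine Optional [evidence_engine()] for fast repeated evaluation.
#' @return Scalar log evidence.
#' @export
log_evidence <- function(problem, alpha, beta, engine = NULL) {
  stopifnot(is_standardized(problem), alpha > 0, beta > 0)
  if (!is.null(engine)) {
    return(evidence_from_engine(engine, alpha, beta)$log_evidence)
  }
  Mt <- problem_matrix(problem)
  ut <- problem$ut
  A <- beta * crossprod(Mt)
  diag(A) <- diag(A) + alpha
  R <- tryCatch(chol(A), error = function(e) {
    stop("Cholesky factorization of the posterior Hessian failed: ",
         conditionMessage(e), call. = FALSE)
  })
  f <- backsolve(R, forwardsolve(t(R), beta * crossprod(Mt, ut)))[, 1]
  E_f <- sum(f^2) / 2
  E_u <- sum((Mt %*% f - ut)^2) / 2
  logdet <- 2 * sum(log(diag(R)))
  n <- problem$n
  m <- problem$m
  -alpha * E_f - beta * E_u - logdet / 2 +
    n * log(alpha) + m * log(beta) - m * log(2 * pi)
}

#' Precompute the evidence engine
#'
#' Eigendecomposition of `M'M` of the standardized problem. Because the
#' posterior Hessian `alpha I + beta M'M` shares this eigenbasis for every
#' hyperparameter pair, all evidence quantities (MAP solution, penalties,
#' log-determinant, trace of the inverse) become O(n) per evaluation,
#' which makes dense grid scans and optimizer refinement cheap even for
#' thousands of nodes.
#'
#' @param problem A [standardize_problem()] result.
#' @return A `tfm_evidence_engine`.
#' @export
evidence_engine <- function(problem) {
  stopifnot(is_standardized(problem))
  gram <- problem_gram(problem)
  e <- eigen(gram$G, symmetric = TRUE)
  d <- pmax(e$values, 0)
  b <- drop(crossprod(e$vectors, gram$b0))
  # Split the data norm into row-space energy (c2 = squared coefficients
  # on the left singular vectors) and its orthogonal remainder, so the
  # residual can be evaluated without catastrophic cancellation.
  uu <- sum(problem$ut^2)
  pos <- d > max(d) * 1e-12
  c2 <- numeric(length(d))
  c2[pos] <- b[pos]^2 / d[pos]
  d[!pos] <- 0
  b[!pos] <- 0
  uperp2 <- max(uu - sum(c2), 0)
  structure(list(d = d, V = e$vectors, b = b, c2 = c2, uperp2 = uperp2,
                 uu = uu, n = problem$n, m = problem$m),
            class = "tfm_evidence_engine")
}

# All evidence ingredients at (alpha, beta) from the eigen engine. The
# ridge residual is computed in the eigenbasis as c_i * alpha/(alpha +
# beta d_i), which stays accurate when the fit is nearly interpolating.
evidence_from_engine <- function(engine, alpha, beta) {
  d <- engine$d
  denom <- alpha + beta * d
  shrink <- alpha / denom
  E_f <- sum(engine$c2 * d * (beta / denom)^2) / 2
  E_u <- (engine$uperp2 + sum(engine$c2 * shrink^2)) / 2
  logdet <- sum(log(denom))
  gamma_eff <- sum(beta * d / denom)   # effective number of parameters
  lev <- -alpha * E_f - beta * E_u - logdet / 2 +
    engine$n * log(alpha) + engine$m * log(beta) -
    engine$m * log(2 * pi)
  list(log_evidence = lev, E_f = E_f, E_u = E_u, logdet = logdet,
       gamma = gamma_eff, tr_Ainv = sum(1 / denom))
}

# Standardized MAP traction from the engine (eigenbasis -> node basis).
engine_map_std <- function(engine, alpha, beta) {
  drop(engine$V %*% (beta * engine$b / (alpha + beta * engine$d)))
}

#' Estimate the inverse noise variance from background displacements
#'
#' Pools the component-wise sample variance of displacement vectors
#' measured far away from any cell (component means subtracted first) and
#' returns `beta = 1 / variance` in 1/length^2 of the field's unit.
#'
#' @param background A [displacement_field()] or data frame with `ux`,
#'   `uy`; at least 10 vectors.
#' @return Scalar beta.
#' @export
estimate_beta_background <- function(background) {
  ux <- background$ux
  uy <- background$uy
  if (length(ux) < 10) {
    stop("Need at least 10 background displacement vectors.", call. = FALSE)
  }
  ss <- sum((ux - mean(ux))^2) + sum((uy - mean(uy))^2)
  v <- ss / (2 * length(ux) - 2)
  1 / v
}

new_evidence_result <- function(method, alpha, beta, problem, engine,
                                surface, boundary) {
  ev <- evidence_from_engine(engine, alpha, beta)
  f_std <- engine_map_std(engine, alpha, beta)
  f <- f_std / problem$column_spreads
  structure(list(
    method = method,
    alpha = alpha, beta = beta, lambda = alpha / beta,
    log_evidence = ev$log_evidence,
    f_map = f, f_map_std = f_std,
    surface = surface, boundary = boundary,
    E_f = ev$E_f, E_u = ev$E_u, gamma = ev$gamma,
    problem = problem, engine = engine
  ), class = "tfm_evidence")
}

#' @export
print.tfm_evidence <- function(x, ...) {
  cat("<tfm_evidence> ", x$method,
      ": alpha = ", format(x$alpha),
      ", beta = ", format(x$beta),
      ", lambda = ", format(x$lambda),
      "\n  log evidence = ", format(x$log_evidence),
      if (x$boundary) "  [maximum at scan boundary]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Bayesian L2 regularization with measured noise (BL2)
#'
#' Standardizes the problem and maximizes the log evidence over the prior
#' precision alpha alone, with the noise precision beta fixed to a
#' measured value. The scan is a log-spaced grid refined by golden-section
#' search; a maximum on the grid boundary is re-scanned once with expanded
#' bounds and flagged if it persists.
#'
#' @inheritParams solve_l2
#' @param beta Measured inverse noise variance (> 0), e.g. from
#'   [estimate_beta_background()].
#' @param alpha_range Log-scan bounds for alpha.
#' @param n_grid Number of grid points.
#' @param reltol Relative tolerance of the golden-section refinement.
#' @return A `tfm_evidence` result (alpha, beta, `lambda = alpha/beta`,
#'   log evidence, MAP traction in Pa, sampled evidence curve).
#' @export
bl2 <- function(M, u, beta, alpha_range = c(1e-6, 1e6), n_grid = 200L,
                reltol = 1e-4) {
  stopifnot(beta > 0)
  problem <- standardize_problem(M, u)
  engine <- evidence_engine(problem)
  bl2_engine(problem, engine, beta, alpha_range, n_grid, reltol)
}

bl2_engine <- function(problem, engine, beta, alpha_range = c(1e-6, 1e6),
                       n_grid = 200L, reltol = 1e-4) {
  scan <- function(range) {
    la <- seq(log(range[1]), log(range[2]), length.out = n_grid)
    lev <- vapply(la, function(l) {
      evidence_from_engine(engine, exp(l), beta)$log_evidence
    }, numeric(1))
    list(la = la, lev = lev, imax = which.max(lev))
  }
  s <- scan(alpha_range)
  boundary <- FALSE
  if (s$imax %in% c(1L, n_grid)) {
    expanded <- c(alpha_range[1] * 1e-3, alpha_range[2] * 1e3)
    s <- scan(expanded)
    boundary <- s$imax %in% c(1L, n_grid)
  }
  i <- s$imax
  lo <- s$la[max(i - 1L, 1L)]
  hi <- s$la[min(i + 1L, length(s$la))]
  opt <- stats::optimize(function(l) {
    evidence_from_engine(engine, exp(l), beta)$log_evidence
  }, lower = lo, upper = hi, maximum = TRUE, tol = reltol)
  alpha_hat <- exp(opt$maximum)
  surface <- tibble::tibble(alpha = exp(s$la), beta = beta,
                            log_evidence = s$lev)
  new_evidence_result("BL2", alpha_hat, beta, problem, engine, surface,
                      boundary)
}

#' Advanced Bayesian L2 regularization (ABL2)
#'
#' Maximizes the log evidence jointly over `(alpha, beta)`: a coarse 2-D
#' log-grid scan locates the basin, Nelder-Mead refines it in log space,
#' and (optionally) the implicit fixed-point equations
#' `alpha = gamma / (2 E_f)`, `beta = (2m - gamma) / (2 E_u)` (with
#' `gamma` the effective number of parameters, from the exact trace of the
#' inverse Hessian) polish the optimum. Both routes agree to well within a
#' percent on non-degenerate problems.
#'
#' @inheritParams bl2
#' @param beta_range Log-scan bounds for beta.
#' @param n_grid Grid points per axis of the coarse scan.
#' @param method `"grid"` (scan + Nelder-Mead, default) or
#'   `"fixed_point"` (scan + implicit-equation iteration).
#' @return A `tfm_evidence` result with the sampled evidence surface.
#' @export
abl2 <- function(M, u, alpha_range = c(1e-6, 1e6),
                 beta_range = c(1e-6, 1e6), n_grid = 30L,
                 reltol = 1e-4, method = c("grid", "fixed_point")) {
  method <- match.arg(method)
  problem <- standardize_problem(M, u)
  engine <- evidence_engine(problem)
  abl2_engine(problem, engine, alpha_range, beta_range, n_grid, reltol,
              method)
}

abl2_engine <- function(problem, engine, alpha_range = c(1e-6, 1e6),
                        beta_range = c(1e-6, 1e6), n_grid = 30L,
                        reltol = 1e-4, method = "grid") {
  scan <- function(ar, br) {
    la <- seq(log(ar[1]), log(ar[2]), length.out = n_grid)
    lb <- seq(log(br[1]), log(br[2]), length.out = n_grid)
    lev <- matrix(NA_real_, n_grid, n_grid)
    for (i in seq_len(n_grid)) {
      for (j in seq_len(n_grid)) {
        lev[i, j] <- evidence_from_engine(engine, exp(la[i]),
                                          exp(lb[j]))$log_evidence
      }
    }
    ij <- which(lev == max(lev), arr.ind = TRUE)[1, ]
    list(la = la, lb = lb, lev = lev, i = ij[1], j = ij[2])
  }
  s <- scan(alpha_range, beta_range)
  boundary <- FALSE
  if (s$i %in% c(1L, n_grid) || s$j %in% c(1L, n_grid)) {
    s <- scan(c(alpha_range[1] * 1e-3, alpha_range[2] * 1e3),
              c(beta_range[1] * 1e-3, beta_range[2] * 1e3))
    boundary <- s$i %in% c(1L, n_grid) || s$j %in% c(1L, n_grid)
  }
  start <- c(s$la[s$i], s$lb[s$j])

  if (method == "grid") {
    opt <- stats::optim(start, function(p) {
      -evidence_from_engine(engine, exp(p[1]), exp(p[2]))$log_evidence
    }, method = "Nelder-Mead",
    control = list(reltol = reltol^2, maxit = 2000))
    alpha_hat <- exp(opt$par[1])
    beta_hat <- exp(opt$par[2])
  } else {
    alpha_hat <- exp(start[1])
    beta_hat <- exp(start[2])
    for (it in seq_len(500L)) {
      ev <- evidence_from_engine(engine, alpha_hat, beta_hat)
      alpha_new <- ev$gamma / (2 * ev$E_f)
      beta_new <- (2 * engine$m - ev$gamma) / (2 * ev$E_u)
      rel <- max(abs(alpha_new - alpha_hat) / alpha_hat,
                 abs(beta_new - beta_hat) / beta_hat)
      alpha_hat <- alpha_new
      beta_hat <- beta_new
      if (rel < 1e-10) break
    }
  }
  surface <- tibble::tibble(
    alpha = rep(exp(s$la), times = n_grid),
    beta = rep(exp(s$lb), each = n_grid),
    log_evidence = as.vector(s$lev)
  )
  new_evidence_result("ABL2", alpha_hat, beta_hat, problem, engine,
                      surface, boundary)
}
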