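#' L-curve criterion for regularization-parameter choice
#'
#' Runs a solver over a log-spaced grid of regularization parameters and
#' records the residual norm and the penalty norm of each solution. On
#' double-logarithmic axes this traces the classical L-curve; the selected
#' parameter sits at the point of maximum curvature ("corner") of the
#' spline-smoothed curve. The corner does not always exist: if the
#' curvature has no interior maximum, or several local maxima of
#' comparable height (within 10 percent), no corner is returned and all
#' candidates are reported instead.
#'
#' @param M A [forward_operator] or matrix.
#' @param u A [displacement_field()] or numeric vector.
#' @param solver `"L2"`, `"L1"` or `"EN"` (for `"EN"` the grid scans
#'   `lambda1` at fixed `lambda2`), or a function `(M, u, lambda) ->
#'   tfm_fit`.
#' @param lambda_grid Log-spaced grid, length >= 10.
#' @param lambda2 Fixed quadratic weight for `solver = "EN"`.
#' @return A `tfm_lcurve`: tibble (`lambda`, `residual_norm`,
#'   `solution_norm`, `curvature`) with attributes `corner_lambda`
#'   (or `NA`), `corner_method` and `candidates`.
#' @export
l_curve <- function(M, u, solver = "L2",
                    lambda_grid = 10^seq(-6, 6, length.out = 40),
                    lambda2 = NULL) {
  if (length(lambda_grid) < 10) {
    stop("`lambda_grid` must have at least 10 points.", call. = FALSE)
  }
  lambda_grid <- sort(lambda_grid)
  fit_fun <- if (is.function(solver)) {
    solver
  } else {
    switch(solver,
      L2 = function(M, u, l) solve_l2(M, u, l),
      L1 = function(M, u, l) solve_l1(M, u, l),
      EN = function(M, u, l) solve_en(M, u, l, lambda2 %||%
                                        stop("EN needs `lambda2`.",
                                             call. = FALSE)),
      stop("Unknown solver tag: ", solver, call. = FALSE)
    )
  }
  penalty_of <- function(fit) {
    if (identical(fit$method, "L1")) fit$penalty_l1 else fit$penalty_l2
  }
  rows <- purrr::map(lambda_grid, function(l) {
    fit <- tryCatch(fit_fun(M, u, l), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tibble::tibble(lambda = l, residual_norm = fit$residual_norm,
                   solution_norm = penalty_of(fit))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    message(dropped, " grid point(s) dropped due to solver failure.")
  }
  curve <- dplyr::bind_rows(rows)
  if (nrow(curve) < 10) {
    stop("Too few successful solver runs for corner detection.",
         call. = FALSE)
  }
  cd <- lcurve_corner(curve)
  curve$curvature <- cd$curvature
  structure(curve,
            corner_lambda = cd$corner, corner_method = cd$method,
            candidates = cd$candidates,
            class = c("tfm_lcurve", class(curve)))
}

# Maximum curvature of the spline-smoothed log-log curve; raw finite
# differences are noise-dominated on these scales.
lcurve_corner <- function(curve) {
  s <- log10(curve$lambda)
  lx <- log10(pmax(curve$residual_norm, .Machine$double.xmin))
  ly <- log10(pmax(curve$solution_norm, .Machine$double.xmin))
  fit_x <- stats::smooth.spline(s, lx, df = min(8, length(s) - 2))
  fit_y <- stats::smooth.spline(s, ly, df = min(8, length(s) - 2))
  d1x <- stats::predict(fit_x, s, deriv = 1)$y
  d2x <- stats::predict(fit_x, s, deriv = 2)$y
  d1y <- stats::predict(fit_y, s, deriv = 1)$y
  d2y <- stats::predict(fit_y, s, deriv = 2)$y
  kappa <- (d1x * d2y - d1y * d2x) / (d1x^2 + d1y^2)^1.5
  n <- length(kappa)
  interior <- 2:(n - 1)
  is_locmax <- vapply(interior, function(i) {
    kappa[i] >= kappa[i - 1] && kappa[i] >= kappa[i + 1] && kappa[i] > 0
  }, logical(1))
  cand <- interior[is_locmax]
  corner <- NA_real_
  method <- "none"
  if (length(cand) >= 1) {
    best <- cand[which.max(kappa[cand])]
    comparable <- cand[kappa[cand] >= 0.9 * kappa[best]]
    if (length(comparable) == 1) {
      corner <- curve$lambda[best]
      method <- "max_curvature"
    } else {
      method <- "ambiguous"
    }
  }
  list(curvature = kappa, corner = corner, method = method,
       candidates = curve$lambda[cand])
}

#' @export
print.tfm_lcurve <- function(x, ...) {
  corner <- attr(x, "corner_lambda")
  cat("<tfm_lcurve> ", nrow(x), " points; corner = ",
      if (is.na(corner)) paste0("none (", attr(x, "corner_method"), ")")
      else format(corner), "\n", sep = "")
  invisible(x)
}

#' Generalized cross validation for L2 regularization
#'
#' \deqn{GCV(\lambda) = \frac{2m\,\|(I - H(\lambda))u\|^2}
#'   {\mathrm{tr}(I - H(\lambda))^2}, \qquad
#'   H(\lambda) = M (M'M + \lambda I)^{-1} M',}
#' evaluated over the grid through a single singular value decomposition
#' of M. Returns the grid minimizer.
#'
#' @inheritParams l_curve
#' @return A `tfm_gcv` tibble (`lambda`, `gcv`) with attribute
#'   `selected_lambda`.
#' @export
gcv_l2 <- function(M, u, lambda_grid = 10^seq(-6, 6, length.out = 40)) {
  inp <- solver_inputs(M, u)
  lambda_grid <- sort(lambda_grid)
  sv <- svd(inp$M, nu = min(dim(inp$M)), nv = 0)
  d2 <- sv$d^2
  c1 <- drop(crossprod(sv$u, inp$u))
  perp2 <- max(sum(inp$u^2) - sum(c1^2), 0)
  N <- nrow(inp$M)
  score <- vapply(lambda_grid, function(l) {
    shrink <- l / (d2 + l)
    rss <- sum((shrink * c1)^2) + perp2
    tr <- N - sum(d2 / (d2 + l))
    N * rss / tr^2
  }, numeric(1))
  out <- tibble::tibble(lambda = lambda_grid, gcv = score)
  structure(out,
            selected_lambda = lambda_grid[which.min(score)],
            class = c("tfm_gcv", class(out)))
}

#' @export
print.tfm_gcv <- function(x, ...) {
  cat("<tfm_gcv> selected lambda =", format(attr(x, "selected_lambda")),
      "\n")
  invisible(x)
}
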