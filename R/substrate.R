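#' Linear elastic half-space substrate
#'
#' Material constants of the gel substrate, modelled as a homogeneous,
#' isotropic, linear elastic half-space.
#'
#' @param youngs_modulus Young's modulus E in Pa. Must be positive.
#' @param poisson_ratio Poisson's ratio, dimensionless, in `[0, 0.5]`.
#'
#' @return An object of class `elastic_substrate`.
#' @examples
#' elastic_substrate(10e3, 0.3)
#' @export
elastic_substrate <- function(youngs_modulus, poisson_ratio) {
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1,
            is.finite(youngs_modulus),
            is.numeric(poisson_ratio), length(poisson_ratio) == 1,
            is.finite(poisson_ratio))
  if (youngs_modulus <= 0) {
    stop("`youngs_modulus` must be positive.", call. = FALSE)
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("`poisson_ratio` must lie in [0, 0.5].", call. = FALSE)
  }
  structure(
    list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio),
    class = "elastic_substrate"
  )
}

#' @export
print.elastic_substrate <- function(x, ...) {
  cat("<elastic_substrate> E =", x$youngs_modulus,
      "Pa, nu =", x$poisson_ratio, "\n")
  invisible(x)
}

#' Boussinesq surface Green's tensor
#'
#' Tangential surface displacement response of an elastic half-space to a
#' tangential point force on its surface:
#' \deqn{G_{ij}(x) = \frac{1+\nu}{\pi E}\left[(1-\nu)\frac{\delta_{ij}}{r}
#'   + \nu \frac{x_i x_j}{r^3}\right].}
#' Units are length per stress for whatever consistent length unit `x`
#' carries.
#'
#' @param x Numeric length-2 separation vector. Must be nonzero; the
#'   self-term of the discretized operator is obtained by shape-function
#'   integration, never from a pointwise evaluation (see
#'   [assemble_direct()]).
#' @param substrate An [elastic_substrate()].
#'
#' @return A symmetric 2 x 2 matrix.
#' @export
greens_tensor <- function(x, substrate) {
  stopifnot(inherits(substrate, "elastic_substrate"),
            is.numeric(x), length(x) == 2, all(is.finite(x)))
  if (sum(x^2) == 0) {
    stop("Green's function is singular at zero separation; ",
         "the self-term must come from shape-function integration.",
         call. = FALSE)
  }
  g <- greens_components(x[1], x[2],
                         substrate$youngs_modulus, substrate$poisson_ratio)
  matrix(c(g$gxx, g$gxy, g$gxy, g$gyy), 2, 2)
}

# Vectorized components of the Green's tensor. dx, dy must not both be 0.
greens_components <- function(dx, dy, E, nu) {
  r2 <- dx^2 + dy^2
  r <- sqrt(r2)
  pref <- (1 + nu) / (pi * E)
  iso <- (1 - nu) / r
  list(gxx = pref * (iso + nu * dx^2 / (r * r2)),
       gyy = pref * (iso + nu * dy^2 / (r * r2)),
       gxy = pref * nu * dx * dy / (r * r2))
}

# Exact mean of the Green's tensor over a square cell centered at the
# singularity, via the angular reduction: G(rho n) * rho is independent of
# rho, so the cell integral collapses to a 1-D integral of the
# center-to-edge distance over the polar angle.
greens_cell_mean <- function(delta, substrate) {
  E <- substrate$youngs_modulus
  nu <- substrate$poisson_ratio
  n_th <- 4096L
  th <- (seq_len(n_th) - 0.5) * (2 * pi / n_th)
  ell <- (delta / 2) / pmax(abs(cos(th)), abs(sin(th)))
  dth <- 2 * pi / n_th
  pref <- (1 + nu) / (pi * E)
  gxx <- pref * sum(((1 - nu) + nu * cos(th)^2) * ell) * dth / delta^2
  gyy <- pref * sum(((1 - nu) + nu * sin(th)^2) * ell) * dth / delta^2
  gxy <- pref * nu * sum(cos(th) * sin(th) * ell) * dth / delta^2
  list(gxx = gxx, gyy = gyy, gxy = gxy)
}

# Gauss-Legendre cell averages of the Green's tensor over square cells of
# side `delta` centered at (cx, cy) (none of which may contain the origin).
greens_cell_mean_offset <- function(cx, cy, delta, substrate, n_gauss = 10L) {
  gl <- gauss_legendre(n_gauss, -delta / 2, delta / 2)
  E <- substrate$youngs_modulus
  nu <- substrate$poisson_ratio
  gxx <- gyy <- gxy <- numeric(length(cx))
  w2 <- outer(gl$w, gl$w)
  X <- outer(gl$x, rep(1, n_gauss))
  Y <- outer(rep(1, n_gauss), gl$x)
  for (k in seq_along(cx)) {
    g <- greens_components(cx[k] + X, cy[k] + Y, E, nu)
    gxx[k] <- sum(w2 * g$gxx)
    gyy[k] <- sum(w2 * g$gyy)
    gxy[k] <- sum(w2 * g$gxy)
  }
  list(gxx = gxx / delta^2, gyy = gyy / delta^2, gxy = gxy / delta^2)
}

# Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(n, a = -1, b = 1) {
  # Golub-Welsch via the symmetric Jacobi matrix.
  if (n == 1) {
    x <- 0
    w <- 2
  } else {
    i <- seq_len(n - 1)
    bet <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- bet
    J[cbind(i + 1, i)] <- bet
    e <- eigen(J, symmetric = TRUE)
    x <- rev(e$values)
    w <- 2 * rev(e$vectors[1, ]^2)
  }
  list(x = (a + b) / 2 + (b - a) / 2 * x, w = w * (b - a) / 2)
}
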