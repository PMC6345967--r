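# Orthonormal Daubechies-4 discrete wavelet transform with periodic
# boundary handling, used by the proximal-gradient solvers. Implemented as
# a plain orthogonal linear map: the analysis step is the classic 4-tap
# polyphase filter pair, the synthesis step its transpose, so forward and
# inverse are exact mutual inverses and both preserve the l2 norm.

d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

# One periodic analysis step along a vector of even length N >= 4.
d4_step <- function(x) {
  f <- d4_filters()
  N <- length(x)
  k <- seq(1, N, by = 2)
  idx <- function(off) x[(k + off - 1) %% N + 1]
  a <- f$h[1] * idx(0) + f$h[2] * idx(1) + f$h[3] * idx(2) + f$h[4] * idx(3)
  d <- f$g[1] * idx(0) + f$g[2] * idx(1) + f$g[3] * idx(2) + f$g[4] * idx(3)
  c(a, d)
}

# Transpose (synthesis) of d4_step.
d4_istep <- function(y) {
  f <- d4_filters()
  N <- length(y)
  half <- N / 2
  a <- y[seq_len(half)]
  d <- y[half + seq_len(half)]
  x <- numeric(N)
  k <- seq(1, N, by = 2)
  for (i in 1:4) {
    pos <- (k + i - 2) %% N + 1
    contrib <- f$h[i] * a + f$g[i] * d
    # accumulate with possible duplicate positions handled via tapply-free sum
    x[pos] <- x[pos] + contrib
  }
  x
}

max_dwt_levels <- function(n) {
  lev <- 0L
  while (n %% 2 == 0 && n / 2 >= 4) {
    lev <- lev + 1L
    n <- n / 2
  }
  lev
}

#' 2-D periodic Daubechies-4 wavelet transform
#'
#' Separable multiresolution transform of a matrix: each level filters the
#' rows and columns of the current approximation block. The map is
#' orthonormal, so `dwt2(x)` preserves the Frobenius norm and
#' `idwt2(dwt2(x))` reconstructs `x` to machine precision. Dimensions must
#' be even and support at least one level (>= 8, or exactly 4, per axis is
#' typical; the level count is the largest `J` with `n / 2^J >= 4`).
#'
#' @param x Numeric matrix.
#' @param levels Number of decomposition levels; default full depth.
#' @return Matrix of wavelet coefficients (same dimension).
#' @export
dwt2 <- function(x, levels = NULL) {
  stopifnot(is.matrix(x))
  J <- levels %||% min(max_dwt_levels(nrow(x)), max_dwt_levels(ncol(x)))
  if (J < 1) stop("Matrix dimensions do not support a DWT level.",
                  call. = FALSE)
  nr <- nrow(x); nc <- ncol(x)
  for (j in seq_len(J)) {
    rr <- seq_len(nr / 2^(j - 1))
    cc <- seq_len(nc / 2^(j - 1))
    blk <- x[rr, cc, drop = FALSE]
    blk <- apply(blk, 2, d4_step)
    blk <- t(apply(blk, 1, d4_step))
    x[rr, cc] <- blk
  }
  attr(x, "levels") <- J
  x
}

#' @rdname dwt2
#' @param w Coefficient matrix from [dwt2()].
#' @export
idwt2 <- function(w, levels = NULL) {
  stopifnot(is.matrix(w))
  J <- levels %||% attr(w, "levels") %||%
    min(max_dwt_levels(nrow(w)), max_dwt_levels(ncol(w)))
  nr <- nrow(w); nc <- ncol(w)
  for (j in rev(seq_len(J))) {
    rr <- seq_len(nr / 2^(j - 1))
    cc <- seq_len(nc / 2^(j - 1))
    blk <- w[rr, cc, drop = FALSE]
    blk <- t(apply(blk, 1, d4_istep))
    blk <- apply(blk, 2, d4_istep)
    w[rr, cc] <- blk
  }
  attr(w, "levels") <- NULL
  w
}
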