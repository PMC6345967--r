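#' @title Discrete forward operator for traction force microscopy
#' @description The 2m x 2n matrix M mapping nodal traction (interleaved
#'   x/y components, units Pa) to sampled displacement (same interleaving,
#'   length unit of the grid). Rows pair with displacement samples, columns
#'   with the pyramidal shape function of each grid node.
#' @name forward_operator
NULL

new_forward_operator <- function(matrix, grid, sample_positions, method,
                                 substrate) {
  structure(
    list(matrix = matrix, grid = grid,
         sample_positions = sample_positions,
         method = method, substrate = substrate,
         unit = grid_unit(grid)),
    class = "forward_operator"
  )
}

#' @export
print.forward_operator <- function(x, ...) {
  cat("<forward_operator> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (", x$method, ", unit ", x$unit, ", mesh ",
      grid_spacing(x$grid), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.forward_operator <- function(x) dim(x$matrix)

is_forward_operator <- function(x) inherits(x, "forward_operator")

# Accept a forward_operator or a plain matrix wherever a solver needs M.
operator_matrix <- function(M) {
  if (is_forward_operator(M)) M$matrix else as.matrix(M)
}

check_units <- function(M, u) {
  if (is_forward_operator(M) && is_displacement_field(u) &&
      !identical(M$unit, field_unit(u))) {
    stop("Mixed-unit algebra: operator is in '", M$unit,
         "' but displacement field is in '", field_unit(u), "'.",
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Kernel K = G * h on a padded oversampled lattice, computed once per grid.
#
# G is sampled in real space on a fine grid (spacing a/oversample) over a
# zero-padded domain (>= pad_factor x extent per axis, so circular
# convolution with the compactly supported pyramid equals the linear one).
# Cells near the singularity are replaced by exact Gauss cell averages and
# the singular cell itself by its angular closed-form mean, after which the
# Riemann-sum convolution is spectrally multiplied by the sampled
# shape-function transform.
# ---------------------------------------------------------------------------
kernel_table <- function(grid, substrate, pad_factor = 2, oversample = 8L,
                         interp_oversample = 4L) {
  assert_regular_grid(grid)
  stopifnot(pad_factor >= 2, oversample >= 2,
            oversample %% interp_oversample == 0)
  a <- grid_spacing(grid)
  dims <- grid_dims(grid)
  delta <- a / oversample
  Nf <- as.integer(2 * pad_factor * (max(dims) - 1) * oversample)
  # FFT-order coordinates (0, delta, ..., -delta)
  idx <- c(0:(Nf / 2), (-(Nf / 2 - 1)):(-1))
  xv <- idx * delta

  E <- substrate$youngs_modulus
  nu <- substrate$poisson_ratio
  DX <- outer(xv, rep(1, Nf))
  DY <- outer(rep(1, Nf), xv)
  R2 <- DX^2 + DY^2
  R2[1, 1] <- 1  # placeholder, fixed below
  R <- sqrt(R2)
  pref <- (1 + nu) / (pi * E)
  Gxx <- pref * ((1 - nu) / R + nu * DX^2 / (R * R2))
  Gyy <- pref * ((1 - nu) / R + nu * DY^2 / (R * R2))
  Gxy <- pref * nu * DX * DY / (R * R2)

  # Exact cell averages close to the singularity, closed-form mean at 0.
  near <- which(R2 <= (2 * a)^2 & !(DX == 0 & DY == 0), arr.ind = TRUE)
  cm <- greens_cell_mean_offset(DX[near], DY[near], delta, substrate)
  Gxx[near] <- cm$gxx; Gyy[near] <- cm$gyy; Gxy[near] <- cm$gxy
  c0 <- greens_cell_mean(delta, substrate)
  Gxx[1, 1] <- c0$gxx; Gyy[1, 1] <- c0$gyy; Gxy[1, 1] <- c0$gxy

  # Sampled pyramid shape function, unit nodal value, support 2a.
  hx <- pmax(0, 1 - abs(xv) / a)
  H <- outer(hx, hx)
  Hhat <- stats::fft(H)

  conv <- function(G) {
    Re(stats::fft(stats::fft(G) * Hhat, inverse = TRUE)) / Nf^2 * delta^2
  }
  Kxx <- conv(Gxx); Kyy <- conv(Gyy); Kxy <- conv(Gxy)

  # Sub-lattice used for shift-theorem interpolation (spacing a / q),
  # cropped to a centered window just covering the attainable separations
  # (grid extent plus a two-mesh margin); the kernel is accurate on the
  # whole padded lattice, so cropping only sets the interpolation period.
  q <- as.integer(interp_oversample)
  step <- oversample %/% q
  Nc <- min(as.integer(2 * (max(dims) + 1) * q), as.integer(Nf %/% step))
  sub_idx <- c(0:(Nc / 2), (-(Nc / 2 - 1)):(-1))  # units of a / q
  pos <- (sub_idx * step) %% Nf + 1L
  list(a = a, delta = delta, Nf = Nf, oversample = oversample,
       q = q, Nc = Nc,
       Kxx = Kxx, Kyy = Kyy, Kxy = Kxy,
       Kxx_c = Kxx[pos, pos], Kyy_c = Kyy[pos, pos], Kxy_c = Kxy[pos, pos],
       half_width = Nf / 2 * delta,
       interp_half_width = Nc / 2 * a / q)
}

# Lookup of the fine-lattice kernel at integer node separations.
kernel_lookup_nodes <- function(kt, dxi, dyi) {
  os <- kt$oversample; Nf <- kt$Nf
  i <- (dxi * os) %% Nf + 1L
  j <- (dyi * os) %% Nf + 1L
  ind <- cbind(as.vector(i), as.vector(j))
  list(xx = matrix(kt$Kxx[ind], nrow(i), ncol(i)),
       yy = matrix(kt$Kyy[ind], nrow(i), ncol(i)),
       xy = matrix(kt$Kxy[ind], nrow(i), ncol(i)))
}

#' Assemble the forward operator on a regular grid (FFT route)
#'
#' Builds M for displacement samples coincident with the traction nodes.
#' Entry blocks are values of the convolution of the Boussinesq Green's
#' function with the pyramidal shape function, computed spectrally on a
#' zero-padded, oversampled lattice.
#'
#' @param grid A regular [traction_grid()].
#' @param substrate An [elastic_substrate()].
#' @param pad_factor Zero-padding factor (>= 2 x domain extent per axis),
#'   suppressing periodic images of the long-ranged kernel.
#' @param oversample Fine-lattice oversampling factor for the kernel.
#' @return A [forward_operator] with `assembly_method = "fft_regular"`.
#' @export
assemble_regular <- function(grid, substrate, pad_factor = 2,
                             oversample = 8L) {
  assert_regular_grid(grid)
  kt <- kernel_table(grid, substrate, pad_factor, oversample)
  dims <- grid_dims(grid)
  a <- kt$a
  ix <- as.integer(round(grid$x / a))
  iy <- as.integer(round(grid$y / a))
  dxi <- outer(ix, ix, `-`)
  dyi <- outer(iy, iy, `-`)
  K <- kernel_lookup_nodes(kt, dxi, dyi)
  M <- interleave_blocks(K$xx, K$xy, K$xy, K$yy)
  op <- new_forward_operator(M, grid, tibble::tibble(x = grid$x, y = grid$y),
                             "fft_regular", substrate)
  op$kernel <- kt
  op
}

# Interleave component blocks (m x n each) into the 2m x 2n operator.
interleave_blocks <- function(xx, xy, yx, yy) {
  m <- nrow(xx); n <- ncol(xx)
  M <- matrix(0, 2 * m, 2 * n)
  ox <- seq(1, 2 * m, by = 2); oy <- ox + 1
  cx <- seq(1, 2 * n, by = 2); cy <- cx + 1
  M[ox, cx] <- xx; M[ox, cy] <- xy
  M[oy, cx] <- yx; M[oy, cy] <- yy
  M
}

#' Assemble the forward operator for irregular sample positions
#'
#' Each sample row is obtained by evaluating the FFT-assembled kernel at an
#' off-lattice point: the kernel spectrum is multiplied by the Fourier
#' shift-theorem phase factor `exp(-i k . dx)` for the sample's fractional
#' lattice offset before inverse transformation. Samples coincident with
#' grid nodes reproduce the regular assembly exactly.
#'
#' @param sample_positions Data frame with columns `x`, `y` (same unit and
#'   origin as the grid) or a [displacement_field()].
#' @inheritParams assemble_regular
#' @param interp_oversample Density of the interpolation lattice relative to
#'   the node lattice (kernel spectrum sampled at spacing
#'   `spacing / interp_oversample`).
#' @return A [forward_operator] with `assembly_method =
#'   "shift_theorem_irregular"`.
#' @export
assemble_irregular <- function(sample_positions, grid, substrate,
                               pad_factor = 2, oversample = 8L,
                               interp_oversample = 4L) {
  assert_regular_grid(grid)
  if (is_displacement_field(sample_positions)) {
    if (!identical(field_unit(sample_positions), grid_unit(grid))) {
      stop("Mixed-unit algebra: sample positions are in '",
           field_unit(sample_positions), "' but the grid is in '",
           grid_unit(grid), "'.", call. = FALSE)
    }
  }
  xs <- sample_positions$x
  ys <- sample_positions$y
  stopifnot(length(xs) >= 1, all(is.finite(xs)), all(is.finite(ys)))
  kt <- kernel_table(grid, substrate, pad_factor, oversample,
                     interp_oversample)
  # Reject samples whose separations could wrap around the interpolation
  # window of the padded kernel lattice.
  ext <- max(max(grid$x) - min(grid$x), max(grid$y) - min(grid$y))
  margin <- min(kt$half_width, kt$interp_half_width) - ext - kt$a
  if (any(xs < min(grid$x) - margin | xs > max(grid$x) + margin |
          ys < min(grid$y) - margin | ys > max(grid$y) + margin)) {
    stop("Sample positions outside the padded domain.", call. = FALSE)
  }

  hc <- kt$a / kt$q
  Nc <- kt$Nc
  q <- kt$q
  Na <- Nc %/% q  # coarse (node-spacing) interpolation period
  kfreq <- c(0:(Nc / 2), (-(Nc / 2 - 1)):(-1))
  nyq <- Nc / 2 + 1L  # Nyquist mode: interpolated with its cosine part
                      # so the interpolant stays real and even
  # Pack Kxx and Kyy into one complex spectrum; Kxy separately.
  S1 <- stats::fft(kt$Kxx_c + 1i * kt$Kyy_c)
  S2 <- stats::fft(kt$Kxy_c)

  n <- n_nodes(grid)
  m <- length(xs)
  M <- matrix(0, 2 * m, 2 * n)
  cx <- seq(1, 2 * n, by = 2); cy <- cx + 1
  a <- kt$a
  ixn <- as.integer(round(grid$x / a))
  iyn <- as.integer(round(grid$y / a))

  base_x <- floor(xs / a); dx_frac <- xs - base_x * a
  base_y <- floor(ys / a); dy_frac <- ys - base_y * a
  # Per-sample shift phases, vectorized over samples.
  PX <- exp((2i * pi / (Nc * hc)) * outer(kfreq, dx_frac))
  PY <- exp((2i * pi / (Nc * hc)) * outer(kfreq, dy_frac))
  PX[nyq, ] <- cos(pi * dx_frac / hc)
  PY[nyq, ] <- cos(pi * dy_frac / hc)

  # Fold frequencies congruent mod Na along one axis (rows), i.e. decimate
  # the interpolant to every q-th lattice point before transforming.
  fold_rows <- function(W) {
    dim(W) <- c(Na, q, ncol2 <- length(W) / (Na * q))
    out <- W[, 1, ]
    for (r in 2:q) out <- out + W[, r, ]
    out
  }

  for (s in seq_len(m)) {
    # Shift by the fractional offset within a mesh cell, then evaluate on
    # the node lattice only: phase-multiply, fold both axes, small IFFT.
    px <- PX[, s]
    py <- PY[, s]
    W1 <- fold_rows(S1 * px)                 # Nc x Nc -> Na x Nc
    W2 <- fold_rows(S2 * px)
    W1 <- t(fold_rows(t(W1) * py))           # -> Na x Na
    W2 <- t(fold_rows(t(W2) * py))
    K1 <- stats::fft(W1, inverse = TRUE) / Nc^2
    K2 <- Re(stats::fft(W2, inverse = TRUE)) / Nc^2
    di <- (as.integer(base_x[s]) - ixn) %% Na + 1L
    dj <- (as.integer(base_y[s]) - iyn) %% Na + 1L
    ind <- cbind(di, dj)
    kxx <- Re(K1[ind]); kyy <- Im(K1[ind]); kxy <- K2[ind]
    M[2 * s - 1, cx] <- kxx
    M[2 * s - 1, cy] <- kxy
    M[2 * s, cx] <- kxy
    M[2 * s, cy] <- kyy
  }
  new_forward_operator(M, grid,
                       tibble::tibble(x = xs, y = ys),
                       "shift_theorem_irregular", substrate)
}

#' Assemble the forward operator by direct numerical quadrature
#'
#' Slow reference assembler: every entry is a 2-D quadrature of the
#' Green's function against the pyramidal shape function of its node,
#' \eqn{\int G(x_s - x') h_j(x') d^2x'}. Cells whose shape-function support
#' contains the sample point are integrated in polar coordinates centred on
#' the singularity (where `G(rho n) rho` is bounded), all other entries by
#' per-quadrant Gauss-Legendre quadrature. Deterministic; intended as the
#' oracle for the fast assemblers on small grids.
#'
#' @inheritParams assemble_irregular
#' @param quad_order Gauss order per quadrant axis (>= 2); the polar rule
#'   uses `16 * quad_order` nodes per direction.
#' @return A [forward_operator] with `assembly_method = "direct_quadrature"`.
#' @export
assemble_direct <- function(sample_positions, grid, substrate,
                            quad_order = 8L) {
  assert_regular_grid(grid)
  stopifnot(quad_order >= 2)
  xs <- sample_positions$x
  ys <- sample_positions$y
  a <- grid_spacing(grid)
  E <- substrate$youngs_modulus
  nu <- substrate$poisson_ratio
  n <- n_nodes(grid)
  m <- length(xs)

  # Gauss rule per quadrant, on [0, a]^2 then reflected.
  gl <- gauss_legendre(quad_order, 0, a)
  qx <- outer(gl$x, rep(1, quad_order))
  qy <- outer(rep(1, quad_order), gl$x)
  qw <- outer(gl$w, gl$w)
  hq <- (1 - qx / a) * (1 - qy / a)
  signs <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))

  # Dense polar rule for singular entries.
  n_th <- 16L * quad_order
  n_rho <- 16L * quad_order
  th <- (seq_len(n_th) - 0.5) * (2 * pi / n_th)
  dth <- 2 * pi / n_th
  cth <- cos(th); sth <- sin(th)
  pref <- (1 + nu) / (pi * E)

  Kxx <- matrix(0, m, n); Kyy <- matrix(0, m, n); Kxy <- matrix(0, m, n)
  for (j in seq_len(n)) {
    xj <- grid$x[j]; yj <- grid$y[j]
    dx <- xs - xj; dy <- ys - yj
    inside <- abs(dx) < a & abs(dy) < a
    for (s in which(!inside)) {
      acc <- c(0, 0, 0)
      for (qd in seq_len(4)) {
        px <- signs[qd, 1] * qx; py <- signs[qd, 2] * qy
        g <- greens_components(dx[s] - px, dy[s] - py, E, nu)
        acc <- acc + c(sum(qw * g$gxx * hq), sum(qw * g$gyy * hq),
                       sum(qw * g$gxy * hq))
      }
      Kxx[s, j] <- acc[1]; Kyy[s, j] <- acc[2]; Kxy[s, j] <- acc[3]
    }
    for (s in which(inside)) {
      # Polar around the sample point; h(x_s + rho n - x_j) integrated in
      # rho up to the support boundary by a dense midpoint rule.
      rb <- ray_to_box(dx[s], dy[s], cth, sth, a)
      rho_nodes <- outer((seq_len(n_rho) - 0.5) / n_rho, rb)
      drho <- rb / n_rho
      hx <- pmax(1 - abs(dx[s] + t(rho_nodes) * cth) / a, 0)
      hy <- pmax(1 - abs(dy[s] + t(rho_nodes) * sth) / a, 0)
      hint <- rowSums(hx * hy) * drho  # per-theta line integral of h
      Kxx[s, j] <- pref * sum(((1 - nu) + nu * cth^2) * hint) * dth
      Kyy[s, j] <- pref * sum(((1 - nu) + nu * sth^2) * hint) * dth
      Kxy[s, j] <- pref * nu * sum(cth * sth * hint) * dth
    }
  }
  M <- interleave_blocks(Kxx, Kxy, Kxy, Kyy)
  new_forward_operator(M, grid, tibble::tibble(x = xs, y = ys),
                       "direct_quadrature", substrate)
}

# Distance from interior point (px, py) of the box [-a, a]^2 to its
# boundary along each direction (ct, st).
ray_to_box <- function(px, py, ct, st, a) {
  tx <- ifelse(ct > 0, (a - px) / ct, ifelse(ct < 0, (-a - px) / ct, Inf))
  ty <- ifelse(st > 0, (a - py) / st, ifelse(st < 0, (-a - py) / st, Inf))
  pmin(tx, ty)
}

#' Predict displacements from a traction vector
#'
#' Evaluates the noise-free forward map `u = M f`.
#'
#' @param object A [forward_operator].
#' @param f Interleaved traction vector of length `2 n`.
#' @param ... Unused.
#' @return A tibble with the sample positions and predicted `ux`, `uy`.
#' @export
predict.forward_operator <- function(object, f, ...) {
  f <- as.numeric(f)
  if (length(f) != ncol(object$matrix)) {
    stop("Traction vector has length ", length(f), " but the operator has ",
         ncol(object$matrix), " columns.", call. = FALSE)
  }
  u <- drop(object$matrix %*% f)
  out <- tibble::tibble(
    x = object$sample_positions$x,
    y = object$sample_positions$y,
    ux = u[seq(1, length(u), by = 2)],
    uy = u[seq(2, length(u), by = 2)]
  )
  displacement_field(out, unit = object$unit)
}

#' Save / load a forward operator
#'
#' The matrix is stored as flat little-endian doubles (column-major) next to
#' a JSON sidecar carrying the grid spacing, units, elastic constants,
#' sample positions and assembly method, so solver runs are reproducible
#' without re-assembly.
#'
#' @param op A [forward_operator].
#' @param path Base path; `<path>.bin` and `<path>.json` are written.
#' @return `write_operator` returns `path` invisibly; `read_operator`
#'   returns the restored operator.
#' @export
write_operator <- function(op, path) {
  stopifnot(is_forward_operator(op))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(op$matrix), con, size = 8, endian = "little")
  meta <- list(
    dim = dim(op$matrix),
    spacing = grid_spacing(op$grid),
    grid_dims = grid_dims(op$grid),
    unit = op$unit,
    youngs_modulus = op$substrate$youngs_modulus,
    poisson_ratio = op$substrate$poisson_ratio,
    method = op$method,
    sample_x = op$sample_positions$x,
    sample_y = op$sample_positions$y
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_operator
#' @export
read_operator <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$dim), size = 8,
                  endian = "little")
  grid <- traction_grid(
    extent = (meta$grid_dims - 1) * meta$spacing,
    spacing = meta$spacing, unit = meta$unit
  )
  sub <- elastic_substrate(meta$youngs_modulus, meta$poisson_ratio)
  new_forward_operator(matrix(vals, meta$dim[1], meta$dim[2]), grid,
                       tibble::tibble(x = meta$sample_x, y = meta$sample_y),
                       meta$method, sub)
}
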