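test_that("Green's tensor matches the closed form and its symmetries", {
  sub <- elastic_substrate(10e3, 0.3)

  # hand-evaluated at x = (3, 4), r = 5
  G <- greens_tensor(c(3, 4), sub)
  pref <- 1.3 / (pi * 1e4)
  expect_equal(G[1, 1], pref * (0.7 / 5 + 0.3 * 9 / 125), tolerance = 1e-14)
  expect_equal(G[2, 2], pref * (0.7 / 5 + 0.3 * 16 / 125), tolerance = 1e-14)
  expect_equal(G[1, 2], pref * 0.3 * 12 / 125, tolerance = 1e-14)
  expect_identical(G[1, 2], G[2, 1])

  # nu = 0 collapses to the isotropic kernel
  sub0 <- elastic_substrate(2e3, 0)
  G0 <- greens_tensor(c(1.3, -2.1), sub0)
  r <- sqrt(1.3^2 + 2.1^2)
  expect_equal(G0, diag(2) / (pi * 2e3 * r), tolerance = 1e-14)

  # on-axis separation has no shear coupling
  expect_identical(greens_tensor(c(2.5, 0), sub)[1, 2], 0)

  # rotation equivariance G(Rx) = R G(x) R'
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  x <- c(0.7, -1.9)
  expect_equal(greens_tensor(drop(R %*% x), sub),
               R %*% greens_tensor(x, sub) %*% t(R), tolerance = 1e-12)

  # 1/E scaling
  expect_equal(greens_tensor(c(1, 2), elastic_substrate(20e3, 0.3)),
               greens_tensor(c(1, 2), sub) / 2, tolerance = 1e-14)

  expect_error(greens_tensor(c(0, 0), sub), "singular")
  expect_error(elastic_substrate(-1, 0.3), "positive")
  expect_error(elastic_substrate(1e4, 0.7), "0, 0.5")
})

test_that("FFT-assembled regular operator agrees with direct quadrature", {
  sub <- default_substrate()
  g <- traction_grid(7, 1, unit = "um")  # 8 x 8 nodes
  op_f <- assemble_regular(g, sub)
  op_d <- assemble_direct(g, g, sub, quad_order = 8)
  rel <- norm(op_f$matrix - op_d$matrix, "F") / norm(op_d$matrix, "F")
  expect_lt(rel, 0.01)

  # coincident-grid operator is symmetric
  expect_lt(max(abs(op_f$matrix - t(op_f$matrix))) / max(abs(op_f$matrix)),
            1e-12)

  # linearity: zero traction maps to zero displacement
  u0 <- predict(op_f, numeric(ncol(op_f$matrix)))
  expect_true(all(u0$ux == 0 & u0$uy == 0))

  # doubling E halves every entry
  op2 <- assemble_regular(g, elastic_substrate(2 * sub$youngs_modulus,
                                               sub$poisson_ratio))
  expect_equal(op2$matrix, op_f$matrix / 2, tolerance = 1e-12)

  # a 1-node (degenerate) grid cannot be constructed
  expect_error(traction_grid(1, 2), "integer multiple")
  expect_error(assemble_regular(data.frame(x = 1, y = 1), sub),
               "traction_grid")
})

test_that("direct quadrature self-converges and matches midpoint far away", {
  sub <- default_substrate()
  g <- traction_grid(7, 1, unit = "um")
  pts <- data.frame(x = c(0.5, 3.3, 6.1), y = c(0.5, 2.2, 0.4))
  o8 <- assemble_direct(pts, g, sub, quad_order = 8)
  o16 <- assemble_direct(pts, g, sub, quad_order = 16)
  expect_lt(norm(o8$matrix - o16$matrix, "F") / norm(o16$matrix, "F"), 1e-3)

  # far node: plain midpoint rule over the pyramid support within 1%
  far_node <- which(g$x == 7 & g$y == 7)
  xs <- 0.5; ys <- 0.5
  hgrid <- seq(-1, 1, length.out = 41)[-41] + 1 / 40
  hh <- outer(pmax(1 - abs(hgrid), 0), pmax(1 - abs(hgrid), 0))
  acc <- matrix(0, 2, 2)
  for (i in seq_along(hgrid)) {
    for (j in seq_along(hgrid)) {
      if (hh[i, j] > 0) {
        acc <- acc + hh[i, j] *
          greens_tensor(c(xs - (7 + hgrid[i]), ys - (7 + hgrid[j])), sub)
      }
    }
  }
  acc <- acc * (2 / 40)^2
  blk <- o8$matrix[1:2, (2 * far_node - 1):(2 * far_node)]
  expect_equal(blk, acc, tolerance = 0.01)

  # nu = 0.3 vs nu = 0 differ only through the nu-terms of the kernel
  o_nu0 <- assemble_direct(pts, g, elastic_substrate(10e3, 0), 4)
  expect_false(isTRUE(all.equal(o8$matrix, o_nu0$matrix)))
})

test_that("shift-theorem irregular assembly matches quadrature and limits", {
  sub <- default_substrate()
  g <- traction_grid(7, 1, unit = "um")

  # samples coincident with grid nodes reproduce regular rows exactly
  sel <- c(1L, 12L, 40L, 64L)
  op_r <- assemble_regular(g, sub)
  op_c <- assemble_irregular(data.frame(x = g$x[sel], y = g$y[sel]), g, sub)
  rows <- as.vector(rbind(2 * sel - 1, 2 * sel))
  expect_lt(max(abs(op_c$matrix - op_r$matrix[rows, ])) /
              max(abs(op_r$matrix)), 1e-10)

  # half-mesh offsets and generic interior points match direct quadrature
  pts <- data.frame(x = c(3.5, 2.5, 4.37), y = c(3.5, 5.5, 2.11))
  oi <- assemble_irregular(pts, g, sub)
  od <- assemble_direct(pts, g, sub, quad_order = 12)
  expect_lt(norm(oi$matrix - od$matrix, "F") / norm(od$matrix, "F"), 0.01)

  # translation invariance: only the sample-node separation enters, so a
  # sample at x0 + d against node j equals a sample at x0 - d against the
  # node mirrored about x0 (the kernel is even).
  g1 <- traction_grid(7, 1, unit = "um")
  d <- 0.3
  a1 <- assemble_irregular(data.frame(x = 2 + d, y = 3), g1, sub)
  a4 <- assemble_irregular(data.frame(x = 2 - d, y = 3), g1, sub)
  j <- which(g1$x == 4 & g1$y == 3)   # separation (2 + d) - 4 = -2 + d
  jm <- which(g1$x == 0 & g1$y == 3)  # separation (2 - d) - 0 = +2 - d
  expect_equal(a1$matrix[1:2, (2 * j - 1):(2 * j)],
               a4$matrix[1:2, (2 * jm - 1):(2 * jm)], tolerance = 1e-10)

  expect_error(assemble_irregular(data.frame(x = 40, y = 2), g, sub),
               "padded domain")
})

test_that("far-field displacement approaches the point-force limit", {
  sub <- default_substrate()
  g <- traction_grid(24, 1, unit = "um")  # 25 x 25 nodes
  node <- which(g$x == 12 & g$y == 12)
  f <- numeric(2 * nrow(g))
  f[2 * node - 1] <- 120  # 120 Pa along x at the central node
  far <- data.frame(x = 12 + 10, y = 12 + 3)
  op <- assemble_irregular(far, g, sub)
  u <- predict(op, f)
  # pyramid integral = mesh^2, so the equivalent point force is 120 * 1
  G <- greens_tensor(c(10, 3), sub)
  expect_equal(c(u$ux, u$uy), drop(G %*% c(120, 0)), tolerance = 0.02)
})

test_that("predict is linear and validates dimensions", {
  sub <- default_substrate()
  g <- traction_grid(5, 1, unit = "um")
  op <- assemble_regular(g, sub)
  set.seed(1)
  f1 <- rnorm(ncol(op$matrix))
  f2 <- rnorm(ncol(op$matrix))
  u1 <- predict(op, f1)
  u2 <- predict(op, f2)
  u12 <- predict(op, f1 + f2)
  expect_equal(u12$ux, u1$ux + u2$ux, tolerance = 1e-12)
  expect_equal(u12$uy, u1$uy + u2$uy, tolerance = 1e-12)
  expect_error(predict(op, f1[-1]), "length")
})

test_that("condition number grows under grid refinement", {
  sub <- default_substrate()
  kappas <- vapply(c(3, 1.5, 1), function(sp) {
    op <- assemble_regular(traction_grid(24, sp, unit = "um"), sub)
    kappa(op$matrix, exact = TRUE)
  }, numeric(1))
  expect_true(all(diff(kappas) > 0))
  expect_gt(kappas[3], 1.5 * kappas[1])  # ill-conditioning premise
})

test_that("operator save/load round-trips matrix and metadata", {
  sub <- default_substrate()
  g <- traction_grid(3, 1, unit = "pix")
  op <- assemble_irregular(data.frame(x = c(0.7, 2.2), y = c(1.1, 0.4)),
                           g, sub)
  path <- file.path(tempdir(), "op_test")
  write_operator(op, path)
  op2 <- read_operator(path)
  expect_identical(op2$matrix, op$matrix)
  expect_identical(op2$method, "shift_theorem_irregular")
  expect_equal(attr(op2$grid, "spacing"), 1)
  expect_identical(op2$unit, "pix")
  expect_equal(op2$substrate$poisson_ratio, 0.3)
  expect_equal(op2$sample_positions$x, c(0.7, 2.2))
})

test_that("mixed units between operator and field are refused", {
  sub <- default_substrate()
  g <- traction_grid(3, 1, unit = "um")
  op <- assemble_regular(g, sub)
  f_pix <- displacement_field(
    data.frame(x = g$x, y = g$y, ux = 0 * g$x, uy = 0 * g$x), unit = "pix")
  expect_error(solve_l2(op, f_pix, 1), "Mixed-unit")
  expect_error(assemble_irregular(f_pix, g, sub), "Mixed-unit")
})
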