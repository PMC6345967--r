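test_that("scene presets honour the benchmark protocol", {
  s9 <- make_spot_scene("nine_spot_100Pa", seed = 3)
  expect_equal(nrow(s9), 9)
  expect_true(all(abs(s9$magnitude - 100) < 1e-12))
  expect_equal(attr(s9, "domain"), c(25, 25))

  s15 <- make_spot_scene("fifteen_spot_0_250Pa", seed = 3)
  expect_equal(nrow(s15), 15)
  expect_lte(max(s15$magnitude), 250)
  expect_gte(min(s15$magnitude), 0)
  expect_equal(sort(s15$magnitude), seq(0, 250, length.out = 15))
  expect_true(all(s15$radius == 1))

  # spots non-overlapping and inside the domain
  dd <- as.matrix(dist(cbind(s15$x, s15$y)))
  expect_gte(min(dd[upper.tri(dd)]), 2 * 1)
  expect_true(all(s15$x > 1 & s15$x < 24 & s15$y > 1 & s15$y < 24))

  # deterministic in the seed
  expect_identical(as.data.frame(make_spot_scene("fifteen_spot_0_250Pa",
                                                 seed = 42)),
                   as.data.frame(make_spot_scene("fifteen_spot_0_250Pa",
                                                 seed = 42)))
  expect_false(identical(
    as.data.frame(make_spot_scene("fifteen_spot_0_250Pa", seed = 1)),
    as.data.frame(make_spot_scene("fifteen_spot_0_250Pa", seed = 2))))
})

test_that("analytic disc displacements have the right structure", {
  sub <- default_substrate()
  # zero traction -> zero displacement
  s0 <- make_spot_scene("nine_spot_100Pa", seed = 1, magnitude_scale = 0)
  u0 <- analytic_displacement(s0, data.frame(x = c(1, 12), y = c(3, 20)))
  expect_true(all(u0$ux == 0 & u0$uy == 0))

  # single disc: displacement at the centre is parallel to the traction
  scene <- structure(
    tibble::tibble(x = 12, y = 13, radius = 1, tx = 80, ty = 60,
                   magnitude = 100),
    domain = c(25, 25), substrate = sub, seed = 1L, variant = "custom",
    class = c("spot_scene", "tbl_df", "tbl", "data.frame"))
  uc <- analytic_displacement(scene, data.frame(x = 12, y = 13))
  expect_equal(uc$uy / uc$ux, 60 / 80, tolerance = 1e-10)
  expect_gt(uc$ux, 0)

  # displacement on the disc edge is finite
  ue <- analytic_displacement(scene, data.frame(x = 13, y = 13))
  expect_true(all(is.finite(c(ue$ux, ue$uy))))

  # far field approaches the point-force solution with F = t * area
  qp <- data.frame(x = 12 + 10, y = 13 + 0.5)
  uf <- analytic_displacement(scene, qp)
  G <- greens_tensor(c(-10, -0.5), sub)
  upt <- drop(G %*% c(80, 60)) * pi * 1^2
  expect_equal(c(uf$ux, uf$uy), upt, tolerance = 0.01)
})

test_that("forward model and analytic displacements are consistent", {
  # rasterized scene traction pushed through the assembled operator must
  # reproduce the analytic field (ties forward_model and synthetic
  # together); mesh is fine relative to the spot radius
  sub <- default_substrate()
  # one disc, mesh at 1/16 of the radius so the stair-step rasterization
  # error stays below the consistency tolerance
  scene <- structure(
    tibble::tibble(x = 4, y = 4, radius = 2, tx = 90, ty = 35,
                   magnitude = sqrt(90^2 + 35^2)),
    domain = c(8, 8), substrate = sub, seed = 1L, variant = "custom",
    class = c("spot_scene", "tbl_df", "tbl", "data.frame"))
  grid <- traction_grid(8, 0.125, unit = "um")
  f <- rasterize_scene(scene, grid)
  op <- assemble_regular(grid, sub)
  u_fwd <- predict(op, f)
  u_ana <- analytic_displacement(scene, grid)
  rms <- function(v) sqrt(mean(v^2))
  rel <- rms(c(u_fwd$ux - u_ana$ux, u_fwd$uy - u_ana$uy)) /
    rms(c(u_ana$ux, u_ana$uy))
  expect_lt(rel, 0.02)
})

test_that("sampling is seeded, uniform and at the documented density", {
  scene <- make_spot_scene("fifteen_spot_0_250Pa", seed = 5)
  u1 <- sample_displacements(scene, 2500, seed = 9)
  u2 <- sample_displacements(scene, 2500, seed = 9)
  expect_identical(as.data.frame(u1), as.data.frame(u2))
  expect_equal(attr(u1, "mean_spacing"), 0.5)  # 2500 over 25 um x 25 um

  # doubling m halves the area per sample
  u4 <- sample_displacements(scene, 5000, seed = 9)
  expect_equal(attr(u4, "mean_spacing")^2, attr(u1, "mean_spacing")^2 / 2)

  # empirical nearest-neighbour spacing is at the 0.5 um scale
  nn <- sapply(seq_len(200), function(i) {
    min(sqrt((u1$x[-i][seq(1, 2400, 5)] - u1$x[i])^2 +
               (u1$y[-i][seq(1, 2400, 5)] - u1$y[i])^2))
  })
  expect_lt(mean(nn), 1.2)
  expect_gt(mean(nn), 0.1)
})

test_that("noise model converts between percent and inverse variance", {
  expect_error(noise_spec("percent_of_max", -5), "positive")

  # beta = 400 Pix^-2 corresponds to sigma = 0.05 Pix
  f <- displacement_field(data.frame(x = 1:20, y = 1:20,
                                     ux = rep(1, 20), uy = rep(0.5, 20)),
                          unit = "pix")
  noisy <- add_noise(f, noise_spec("inverse_variance", 400, seed = 1))
  expect_equal(attr(noisy, "noise_sigma"), 0.05)
  expect_equal(attr(noisy, "noise_beta"), 400)

  # percent mode: sigma = level% of the max vector magnitude
  noisy2 <- add_noise(f, noise_spec("percent_of_max", 5, seed = 1))
  expect_equal(attr(noisy2, "noise_sigma"),
               0.05 * max(sqrt(f$ux^2 + f$uy^2)))

  # tiny level leaves the field essentially unchanged
  tiny <- add_noise(f, noise_spec("percent_of_max", 1e-10, seed = 1))
  expect_equal(tiny$ux, f$ux, tolerance = 1e-9)

  # law of large numbers: realized noise std within 1% at 1e6 draws
  big <- displacement_field(data.frame(x = seq_len(5e5), y = seq_len(5e5),
                                       ux = 0, uy = 0), unit = "pix")
  nb <- add_noise(big, noise_spec("inverse_variance", 400, seed = 2))
  expect_equal(sd(c(nb$ux, nb$uy)), 0.05, tolerance = 0.01)
})

test_that("rasterization and patch assignment follow the disc geometry", {
  scene <- structure(
    tibble::tibble(x = 3, y = 3, radius = 1, tx = 50, ty = 0,
                   magnitude = 50),
    domain = c(6, 6), substrate = default_substrate(), seed = 1L,
    variant = "custom",
    class = c("spot_scene", "tbl_df", "tbl", "data.frame"))
  grid <- traction_grid(6, 0.5, unit = "um")
  f <- rasterize_scene(scene, grid)
  lab <- assign_patches(scene, grid)
  inside <- (grid$x - 3)^2 + (grid$y - 3)^2 <= 1
  expect_identical(lab == 1, inside)
  expect_true(all(f[2 * which(inside) - 1] == 50))
  expect_true(all(f[2 * which(!inside) - 1] == 0))
  # boundary node (distance exactly the radius) is inside
  expect_equal(lab[grid$x == 4 & grid$y == 3], 1L)
})
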