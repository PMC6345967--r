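#' Synthetic traction scenes with circular spots
#'
#' Ground-truth benchmark scenes: circular spots, each exerting a uniform
#' tangential traction, on a square elastic domain. The two presets follow
#' the standard artificial-data protocol of this package: a 25 um x 25 um
#' plane on a 10 kPa, nu = 0.3 substrate with spots of 2 um diameter.
#'
#' * `"nine_spot_100Pa"`: 9 spots, each with traction magnitude 100 Pa.
#' * `"fifteen_spot_0_250Pa"`: 15 spots with magnitudes evenly spaced over
#'   0-250 Pa (then shuffled by seed), so very weak spots always exist.
#'
#' Spot centres are rejection-sampled to be non-overlapping with at least
#' one diameter of centre separation; traction directions are uniform
#' random angles. The layout is a deterministic function of `seed`.
#'
#' @param variant Scene preset.
#' @param seed Integer seed controlling layout, directions and magnitude
#'   shuffle.
#' @param domain_size Side length of the square domain (um).
#' @param spot_radius Spot radius (um).
#' @param substrate An [elastic_substrate()]; default E = 10 kPa, nu = 0.3.
#' @param magnitude_scale Optional multiplier applied to all spot
#'   magnitudes (used to probe low signal-to-noise regimes).
#'
#' @return A `spot_scene`: a tibble of spots (`x`, `y`, `radius`, `tx`,
#'   `ty`, `magnitude`) with attributes `domain`, `substrate`, `seed`,
#'   `variant`.
#' @export
make_spot_scene <- function(variant = c("nine_spot_100Pa",
                                        "fifteen_spot_0_250Pa"),
                            seed = 1L,
                            domain_size = 25,
                            spot_radius = 1,
                            substrate = elastic_substrate(10e3, 0.3),
                            magnitude_scale = 1) {
  variant <- match.arg(variant)
  n_spots <- if (variant == "nine_spot_100Pa") 9L else 15L
  mags <- if (variant == "nine_spot_100Pa") {
    rep(100, n_spots)
  } else {
    seq(0, 250, length.out = n_spots)
  }
  withr::with_seed(as.integer(seed), {
    if (variant == "fifteen_spot_0_250Pa") mags <- sample(mags)
    centers <- place_spots(n_spots, domain_size, spot_radius,
                           min_sep = 4 * spot_radius)
    angles <- stats::runif(n_spots, 0, 2 * pi)
  })
  mags <- mags * magnitude_scale
  spots <- tibble::tibble(
    x = centers[, 1], y = centers[, 2], radius = spot_radius,
    tx = mags * cos(angles), ty = mags * sin(angles), magnitude = mags
  )
  structure(spots,
            domain = c(domain_size, domain_size), substrate = substrate,
            seed = as.integer(seed), variant = variant,
            class = c("spot_scene", class(spots)))
}

is_spot_scene <- function(x) inherits(x, "spot_scene")
scene_substrate <- function(scene) attr(scene, "substrate")
scene_domain <- function(scene) attr(scene, "domain")

# Rejection-sample non-overlapping disc centres inside the domain with a
# boundary margin of two radii.
place_spots <- function(n, domain, radius, min_sep) {
  margin <- 2 * radius
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 100000L) {
      stop("Could not place non-overlapping spots; domain too crowded.",
           call. = FALSE)
    }
    p <- stats::runif(2, margin, domain - margin)
    if (placed == 0L ||
        min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            p)^2))) >= min_sep) {
      placed <- placed + 1L
      centers[placed, ] <- p
    }
  }
  centers
}

#' Half-space displacements of a spot scene
#'
#' Displacement field of uniform tangential traction on circular discs,
#' superposed over all spots. For each query point the 2-D disc integral of
#' the Boussinesq Green's function collapses exactly to a 1-D angular
#' integral, because \eqn{G(\rho \hat n)\,\rho} does not depend on
#' \eqn{\rho}; the chord length of each ray through the disc is available
#' in closed form and the remaining smooth angular integral is evaluated by
#' Gauss-Legendre quadrature. Query points on or inside the discs are
#' allowed (the displacement is finite there).
#'
#' @param scene A [make_spot_scene()] scene.
#' @param query_points Data frame with columns `x`, `y` (um).
#' @param n_theta Number of angular quadrature nodes per spot.
#' @return A [displacement_field()] in um.
#' @export
analytic_displacement <- function(scene, query_points, n_theta = 256L) {
  stopifnot(is_spot_scene(scene))
  qx <- query_points$x
  qy <- query_points$y
  sub <- scene_substrate(scene)
  E <- sub$youngs_modulus
  nu <- sub$poisson_ratio
  pref <- (1 + nu) / (pi * E)
  ux <- numeric(length(qx))
  uy <- numeric(length(qx))

  for (k in seq_len(nrow(scene))) {
    tx <- scene$tx[k]; ty <- scene$ty[k]
    if (tx == 0 && ty == 0) next
    R <- scene$radius[k]
    wx <- scene$x[k] - qx
    wy <- scene$y[k] - qy
    d <- sqrt(wx^2 + wy^2)
    inside <- d <= R
    phi <- atan2(wy, wx)
    Ixx <- Iyy <- Ixy <- numeric(length(qx))

    if (any(inside)) {
      gl <- gauss_legendre(n_theta, 0, 2 * pi)
      ii <- which(inside)
      for (q in seq_len(n_theta)) {
        th <- gl$x[q]; w <- gl$w[q]
        ct <- cos(th); st <- sin(th)
        nw <- ct * wx[ii] + st * wy[ii]
        ell <- nw + sqrt(pmax(nw^2 - (d[ii]^2 - R^2), 0))
        Ixx[ii] <- Ixx[ii] + w * ((1 - nu) + nu * ct^2) * ell
        Iyy[ii] <- Iyy[ii] + w * ((1 - nu) + nu * st^2) * ell
        Ixy[ii] <- Ixy[ii] + w * nu * ct * st * ell
      }
    }
    if (any(!inside)) {
      # Exterior: rays hit the disc within |psi| < asin(R/d) around the
      # centre direction; substituting psi = theta_c sin(t) removes the
      # square-root endpoint kink.
      oo <- which(!inside)
      thc <- asin(pmin(R / d[oo], 1))
      gl <- gauss_legendre(n_theta, -pi / 2, pi / 2)
      for (q in seq_len(n_theta)) {
        t0 <- gl$x[q]; w <- gl$w[q]
        psi <- thc * sin(t0)
        jac <- thc * cos(t0)
        th <- phi[oo] + psi
        ct <- cos(th); st <- sin(th)
        nw <- d[oo] * cos(psi)
        disc <- pmax(nw^2 - (d[oo]^2 - R^2), 0)
        ell <- 2 * sqrt(disc) * jac
        Ixx[oo] <- Ixx[oo] + w * ((1 - nu) + nu * ct^2) * ell
        Iyy[oo] <- Iyy[oo] + w * ((1 - nu) + nu * st^2) * ell
        Ixy[oo] <- Ixy[oo] + w * nu * ct * st * ell
      }
    }
    ux <- ux + pref * (Ixx * tx + Ixy * ty)
    uy <- uy + pref * (Ixy * tx + Iyy * ty)
  }
  displacement_field(tibble::tibble(x = qx, y = qy, ux = ux, uy = uy),
                     unit = "um")
}

#' Sample displacements at random marker positions
#'
#' Emulates fiducial-marker measurements: `m` positions drawn uniformly
#' over the domain, displacement vectors from [analytic_displacement()].
#' At the reference density of one sample per (0.5 um)^2 the mean spacing
#' of markers is about 0.5 um.
#'
#' @param scene A spot scene.
#' @param m Number of samples (>= 1).
#' @param seed Integer seed for the sample positions.
#' @param n_theta Passed to [analytic_displacement()].
#' @return A [displacement_field()] in um, with attribute `mean_spacing`
#'   (domain area / m, square-rooted).
#' @export
sample_displacements <- function(scene, m, seed = 1L, n_theta = 256L) {
  stopifnot(is_spot_scene(scene), m >= 1)
  dom <- scene_domain(scene)
  withr::with_seed(as.integer(seed), {
    pts <- tibble::tibble(x = stats::runif(m, 0, dom[1]),
                          y = stats::runif(m, 0, dom[2]))
  })
  u <- analytic_displacement(scene, pts, n_theta = n_theta)
  attr(u, "mean_spacing") <- sqrt(prod(dom) / m)
  attr(u, "sampling_seed") <- as.integer(seed)
  u
}

#' Noise specification for displacement data
#'
#' @param mode `"percent_of_max"`: the standard deviation is `level`
#'   percent of the maximal displacement vector magnitude of the noise-free
#'   field. `"inverse_variance"`: `level` is the inverse noise variance
#'   beta (1/length^2), i.e. sigma = 1/sqrt(beta).
#' @param level Positive noise level (percent, or beta).
#' @param seed Integer seed for the noise draw.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(mode = c("percent_of_max", "inverse_variance"),
                       level, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(level), length(level) == 1)
  if (!is.finite(level) || level <= 0) {
    stop("Noise `level` must be positive.", call. = FALSE)
  }
  structure(list(mode = mode, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add i.i.d. Gaussian noise to a displacement field
#'
#' Zero-mean Gaussian noise is added to every displacement component. The
#' realized sigma and the equivalent inverse variance beta = 1/sigma^2 are
#' recorded as attributes `noise_sigma` and `noise_beta` (in the field's
#' length unit).
#'
#' @param u A [displacement_field()]. For `percent_of_max` this must be the
#'   noise-free field.
#' @param spec A [noise_spec()].
#' @return The noisy `displacement_field`.
#' @export
add_noise <- function(u, spec) {
  stopifnot(is_displacement_field(u), inherits(spec, "noise_spec"))
  sigma <- switch(spec$mode,
    percent_of_max = spec$level / 100 * max(sqrt(u$ux^2 + u$uy^2)),
    inverse_variance = 1 / sqrt(spec$level)
  )
  out <- tibble::as_tibble(u)
  withr::with_seed(spec$seed, {
    out$ux <- out$ux + stats::rnorm(nrow(out), 0, sigma)
    out$uy <- out$uy + stats::rnorm(nrow(out), 0, sigma)
  })
  res <- displacement_field(out, unit = field_unit(u),
                            pixel_size = attr(u, "pixel_size"))
  attr(res, "noise_sigma") <- sigma
  attr(res, "noise_beta") <- 1 / sigma^2
  attr(res, "noise_seed") <- spec$seed
  res
}

#' Rasterize scene traction onto a grid
#'
#' Ground-truth nodal traction: a node whose centre lies inside (or on the
#' boundary of) a spot receives that spot's traction vector, otherwise
#' zero.
#'
#' @param scene A spot scene.
#' @param grid A [traction_grid()]; if its unit is `"pix"`, positions are
#'   compared after converting the scene with `pixel_size`.
#' @param pixel_size Micrometres per pixel when `grid` is in pixel units.
#' @return Interleaved 2n traction vector (Pa).
#' @export
rasterize_scene <- function(scene, grid, pixel_size = 0.1) {
  stopifnot(is_spot_scene(scene))
  assert_regular_grid(grid)
  fac <- if (grid_unit(grid) == "pix") 1 / pixel_size else 1
  f <- numeric(2 * n_nodes(grid))
  for (k in seq_len(nrow(scene))) {
    inside <- (grid$x - scene$x[k] * fac)^2 +
      (grid$y - scene$y[k] * fac)^2 <= (scene$radius[k] * fac)^2
    f[2 * which(inside) - 1] <- scene$tx[k]
    f[2 * which(inside)] <- scene$ty[k]
  }
  f
}

#' Patch labels for grid nodes from scene geometry
#'
#' @inheritParams rasterize_scene
#' @return Integer vector, one entry per node: 0 for background, or the
#'   spot index whose disc contains the node (boundary inclusive).
#' @export
assign_patches <- function(scene, grid, pixel_size = 0.1) {
  stopifnot(is_spot_scene(scene))
  assert_regular_grid(grid)
  fac <- if (grid_unit(grid) == "pix") 1 / pixel_size else 1
  lab <- integer(n_nodes(grid))
  for (k in rev(seq_len(nrow(scene)))) {
    inside <- (grid$x - scene$x[k] * fac)^2 +
      (grid$y - scene$y[k] * fac)^2 <= (scene$radius[k] * fac)^2
    lab[inside] <- k
  }
  lab
}
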