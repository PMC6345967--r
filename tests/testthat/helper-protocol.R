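# Reference-protocol runs are expensive (full 51x51 grid, 2500 samples,
# a few hundred MB of matrices each), so they are computed once per test
# session, reduced to their scalar outcomes immediately, and the large
# objects are released before the next seed.
.protocol_cache <- new.env(parent = emptyenv())

protocol_summaries <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = "_")
  if (is.null(.protocol_cache[[key]])) {
    rows <- lapply(seeds, function(s) {
      r <- run_reference_protocol(seed = s)
      out <- data.frame(
        seed = s,
        beta_abl2 = r$abl2$beta,
        alpha_abl2 = r$abl2$alpha,
        lambda_abl2 = r$abl2$lambda,
        lambda_bl2 = r$bl2$lambda,
        alpha_bl2 = r$bl2$alpha,
        boundary_abl2 = r$abl2$boundary,
        boundary_bl2 = r$bl2$boundary
      )
      rm(r)
      gc(verbose = FALSE)
      out
    })
    .protocol_cache[[key]] <- do.call(rbind, rows)
  }
  .protocol_cache[[key]]
}

# Log-spaced penalty grids matched to the scale of the raw (unstandardized)
# operator: the L1 path is anchored at the smallest lambda1 with an all-zero
# solution (2 ||M'u||_inf), the L2 path at the largest eigenvalue of M'M.
scaled_lambda_grid <- function(op, u, kind = c("L2", "L1"), n = 12) {
  kind <- match.arg(kind)
  M <- op$matrix
  uv <- as.vector(rbind(u$ux, u$uy))
  if (kind == "L1") {
    top <- 2 * max(abs(crossprod(M, uv)))
    # stay above the near-interpolation regime where coordinate descent
    # needs excessive iterations
    top * 10^seq(-3, -0.25, length.out = n)
  } else {
    top <- bayestfm:::power_iteration_sq(M)
    top * 10^seq(-5, 2, length.out = n)
  }
}

# Small desk-scale variant of the benchmark used where only qualitative
# orderings are asserted: coarser mesh (1 um -> 26 x 26 nodes) and
# moderate undersampling keep solver sweeps fast.
desk_scale_data <- function(seed = 1L, noise_percent = 4, m = 540L,
                            mesh = 1.0, magnitude_scale = 1) {
  scene <- make_spot_scene("fifteen_spot_0_250Pa", seed = seed,
                           magnitude_scale = magnitude_scale)
  field <- sample_displacements(scene, m = m, seed = seed + 11L)
  field <- convert_units(field, "pix", pixel_size = 0.1)
  noisy <- add_noise(field, noise_spec("percent_of_max", noise_percent,
                                       seed = seed + 23L))
  grid <- traction_grid(250, mesh / 0.1, unit = "pix")
  op <- assemble_irregular(noisy, grid, scene_substrate(scene))
  list(scene = scene, field = noisy, grid = grid, op = op,
       f_true = rasterize_scene(scene, grid),
       labels = assign_patches(scene, grid),
       sigma = attr(noisy, "noise_sigma"))
}
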