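#' Run the reference artificial-data benchmark
#'
#' End-to-end pipeline on the standard artificial-data conditions: a
#' 15-spot (0-250 Pa) scene on a 25 um x 25 um, E = 10 kPa, nu = 0.3
#' substrate; displacements sampled at `m` random marker positions
#' (default 2500, i.e. on average every 0.5 um), converted to pixel units
#' (default 0.1 um/Pix) and corrupted with Gaussian noise of inverse
#' variance `beta` (default 400 Pix^-2, sigma = 0.05 Pix); traction
#' discretized on a 0.5 um mesh (51 x 51 nodes); the forward operator
#' assembled with the shift-theorem route; and the Bayesian solvers run on
#' the standardized problem.
#'
#' @param seed Integer master seed; scene, sampling and noise sub-seeds are
#'   derived deterministically from it.
#' @param variant Scene preset, see [make_spot_scene()].
#' @param m Number of displacement samples.
#' @param mesh Traction mesh constant in um.
#' @param pixel_size Micrometres per pixel.
#' @param beta Generating inverse noise variance in Pix^-2.
#' @param magnitude_scale Optional scaling of all spot tractions.
#' @param run_bl2,run_abl2 Which Bayesian solvers to run (BL2 uses the
#'   generating beta as its measured noise level).
#' @return A list with the scene, noisy field (Pix), operator, standardized
#'   problem/engine, `bl2` and `abl2` results, and the ground-truth nodal
#'   traction with patch labels.
#' @export
run_reference_protocol <- function(seed = 1L,
                                   variant = "fifteen_spot_0_250Pa",
                                   m = 2500L, mesh = 0.5,
                                   pixel_size = 0.1, beta = 400,
                                   magnitude_scale = 1,
                                   run_bl2 = TRUE, run_abl2 = TRUE) {
  seed <- as.integer(seed)
  scene <- make_spot_scene(variant, seed = seed,
                           magnitude_scale = magnitude_scale)
  field_um <- sample_displacements(scene, m = m, seed = seed + 1000003L)
  field_pix <- convert_units(field_um, "pix", pixel_size = pixel_size)
  noisy <- add_noise(field_pix,
                     noise_spec("inverse_variance", beta,
                                seed = seed + 2000003L))
  dom <- scene_domain(scene)
  grid <- traction_grid(dom / pixel_size, mesh / pixel_size, unit = "pix")
  op <- assemble_irregular(noisy, grid, scene_substrate(scene))
  problem <- standardize_problem(op, noisy, materialize = FALSE)
  engine <- evidence_engine(problem)

  res_bl2 <- if (run_bl2) bl2_engine(problem, engine, beta) else NULL
  res_abl2 <- if (run_abl2) abl2_engine(problem, engine) else NULL

  f_true <- rasterize_scene(scene, grid, pixel_size = pixel_size)
  labels <- assign_patches(scene, grid, pixel_size = pixel_size)
  list(scene = scene, field = noisy, grid = grid, operator = op,
       problem = problem, engine = engine,
       bl2 = res_bl2, abl2 = res_abl2,
       f_true = f_true, labels = labels,
       seed = seed, beta = beta, pixel_size = pixel_size)
}
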