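# bayestfm

Traction force microscopy (TFM) measures the stress field an adherent
cell exerts on a soft elastic substrate from the displacements of
fiducial markers embedded in the gel. Computing traction from
displacement means inverting a severely ill-conditioned linear system, so
every practical TFM pipeline regularizes — and the choice of the
regularization parameter injects subjectivity that corrupts comparisons
between cells and conditions. `bayestfm` is for researchers analysing
substrate-displacement data who want that choice made automatically and
reproducibly.

The package provides, in one consistent tidyverse-style interface:

* the **elastic half-space forward model**: Boussinesq Green's tensor
  `G_ij(x) = (1+ν)/(πE) [(1−ν)δ_ij/r + ν x_i x_j / r³]` discretized with
  pyramidal shape functions into a dense operator `u = M f + s`, with
  fast FFT assembly on regular grids, a Fourier shift-theorem extension to
  irregular marker positions, and a quadrature reference assembler;
* **five penalized inverse solvers** for
  `argmin_f ||Mf − u||² + λ₁||R₁f||₁ + λ₂||R₂f||₂²`: ridge (L2), Lasso
  (L1), Elastic Net, and two proximal-gradient variants (PGL, PGEN) that
  soft-threshold orthonormal Daubechies-4 wavelet coefficients;
* **classical parameter selection**: L-curve corner detection and
  generalized cross validation;
* **two parameter-free Bayesian solvers**: BL2 (noise precision β
  measured from background displacements, prior precision α from
  evidence maximization) and ABL2 (α and β jointly from the 2-D evidence
  surface), both built on the closed-form log evidence
  `−αE_f − βE_u − ½ log det A + n log α + m log β − m log 2π` with
  `A = αI + βMᵀM`, evaluated through a precomputed eigendecomposition;
  the selected L2 parameter is `λ̂ = α̂/β̂`;
* a **synthetic benchmark generator** (circular traction spots with
  semi-analytic half-space displacements, random marker sampling,
  calibrated Gaussian noise) and the four standard **quality metrics**
  DTMA, DTMB, SNR, DMA;
* tabular text IO for displacement and traction fields and a `tfm`
  command-line front end (`simulate`, `reconstruct`, `bl2`, `abl2`,
  `lcurve`, `gcv`, `evaluate`).

## Worked example

Simulate the fifteen-spot benchmark scene (0–250 Pa spots on a 10 kPa,
ν = 0.3 substrate), sample 600 markers, add noise with inverse variance
β = 400 Pix⁻², assemble the operator on a 1 μm mesh and reconstruct with
ABL2 — no regularization parameter is supplied anywhere:

```r
library(bayestfm)

scene <- make_spot_scene("fifteen_spot_0_250Pa", seed = 7)
field <- sample_displacements(scene, m = 600, seed = 8) |>
  convert_units("pix", pixel_size = 0.1) |>
  add_noise(noise_spec("inverse_variance", 400, seed = 9))

grid <- traction_grid(250, 10, unit = "pix")   # 26 x 26 nodes, 1 um mesh
op <- assemble_irregular(field, grid, scene_substrate(scene))
op
#> <forward_operator> 1200 x 1352 (shift_theorem_irregular, unit pix, mesh 10)

fit <- abl2(op, field)
glance(fit)
#> # A tibble: 1 × 6
#>   method   alpha  beta lambda log_evidence boundary
#>   <chr>    <dbl> <dbl>  <dbl>        <dbl> <lgl>
#> 1 ABL2   203031.  462.   440.        1654. FALSE
```

ABL2 estimated the noise precision from the data alone: β̂ ≈ 462 Pix⁻²
against the generating 400 Pix⁻² (σ̂ = 0.047 vs 0.050 Pix), and selected
the regularization level λ̂ = α̂/β̂ ≈ 440 (standardized units) without
an L-curve or manual input. Comparing the reconstruction against the
known ground truth:

```r
truth  <- rasterize_scene(scene, grid)
labels <- assign_patches(scene, grid)
error_report(fit$f_map, truth, labels)
#> # A tibble: 1 × 4
#>    dtma  dtmb   snr    dma
#>   <dbl> <dbl> <dbl>  <dbl>
#> 1 -0.423 0.195  3.15 -0.199
```

Mean spot traction is underestimated by 42 % (DTMA < 0 — expected for a
ridge-type solution at this coarse 1 μm mesh and light 600-marker
sampling), background contamination is ~20 % of the mean spot signal
(DTMB), spots stand out threefold above the background spread (SNR), and
spot peaks are 20 % low (DMA). `tidy(fit)` returns the per-node traction
table and `autoplot(fit)` the evidence surface; `map_traction_table(fit)`
gives the traction map for plotting.

The same pipeline runs from a shell:

```sh
tfm simulate --variant fifteen_spot_0_250Pa --m 600 --beta 400 --seed 7 --out disp.txt
tfm abl2 --displacements disp.txt --mesh 10 --extent 250 --out traction.txt
```

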