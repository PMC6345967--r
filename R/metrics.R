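#' @title Reconstruction-quality metrics
#' @description Four dimensionless error measures comparing a reconstructed
#'   traction field with the known ground truth, discriminating nodes
#'   inside and outside circular traction patches:
#'   DTMA (deviation of mean traction magnitude at adhesions; 0 is perfect,
#'   negative/positive means under-/overestimation), DTMB (the same
#'   normalized deviation for the background), SNR (mean patch magnitude
#'   over the background spread) and DMA (deviation of the per-patch
#'   traction maxima).
#' @name metrics
NULL

traction_magnitudes <- function(f) {
  tx <- f[seq(1, length(f), 2)]
  ty <- f[seq(2, length(f), 2)]
  sqrt(tx^2 + ty^2)
}

as_traction_vector <- function(f) {
  if (inherits(f, "tfm_fit")) return(f$traction)
  if (is.data.frame(f)) return(as.vector(rbind(f$tx, f$ty)))
  as.numeric(f)
}

check_assignment <- function(labels, f) {
  if (length(labels) * 2 != length(f)) {
    stop("Patch assignment length does not match the traction vector.",
         call. = FALSE)
  }
  if (!any(labels > 0)) stop("No traction patches in assignment.",
                             call. = FALSE)
  invisible(labels)
}

# Per-patch means of |t|, excluding zero-magnitude real patches (guarded).
patch_stats <- function(mag_recon, mag_real, labels, stat) {
  patches <- sort(unique(labels[labels > 0]))
  vals <- purrr::map_dbl(patches, function(p) {
    sel <- labels == p
    denom <- stat(mag_real[sel])
    if (denom <= 0) return(NA_real_)
    (stat(mag_recon[sel]) - denom) / denom
  })
  if (anyNA(vals)) {
    warning("Excluded ", sum(is.na(vals)),
            " patch(es) with zero real traction magnitude.")
  }
  vals[!is.na(vals)]
}

#' Deviation of traction magnitude at adhesions (DTMA)
#'
#' @param recon,real Traction as `tfm_fit`, tibble (`tx`, `ty`) or
#'   interleaved vector, on the same grid.
#' @param assignment Integer patch labels per node (0 = background), e.g.
#'   from [assign_patches()].
#' @return Scalar; 0 for perfect mean recovery.
#' @export
dtma <- function(recon, real, assignment) {
  fr <- as_traction_vector(recon)
  ft <- as_traction_vector(real)
  check_assignment(assignment, fr)
  vals <- patch_stats(traction_magnitudes(fr), traction_magnitudes(ft),
                      assignment, mean)
  mean(vals)
}

#' Deviation of traction magnitude in the background (DTMB)
#'
#' Normalized difference of reconstructed and real traction magnitude
#' outside the patches, with the mean patch magnitude of the real field as
#' normalizer. Magnitudes much smaller than one indicate a clean
#' background.
#'
#' @inheritParams dtma
#' @export
dtmb <- function(recon, real, assignment) {
  fr <- as_traction_vector(recon)
  ft <- as_traction_vector(real)
  check_assignment(assignment, fr)
  bg <- assignment == 0
  if (!any(bg)) stop("Empty background.", call. = FALSE)
  mr <- traction_magnitudes(fr)
  mt <- traction_magnitudes(ft)
  patches <- sort(unique(assignment[assignment > 0]))
  patch_means <- purrr::map_dbl(patches, ~ mean(mt[assignment == .x]))
  mean(mr[bg] - mt[bg]) / mean(patch_means)
}

#' Signal-to-noise ratio of a reconstruction (SNR)
#'
#' Mean patch traction magnitude over the spread of the background
#' traction. The background spread is by default the standard deviation
#' over all background vector components; set
#' `background_std = "magnitude"` for the standard deviation of the
#' background magnitudes instead. A zero background spread returns `Inf`.
#'
#' @inheritParams dtma
#' @param background_std `"components"` (default) or `"magnitude"`.
#' @return Scalar in `[0, Inf]`; values much larger than one indicate good
#'   separation of traction from noise.
#' @export
snr <- function(recon, assignment,
                background_std = c("components", "magnitude")) {
  background_std <- match.arg(background_std)
  fr <- as_traction_vector(recon)
  check_assignment(assignment, fr)
  bg <- assignment == 0
  if (sum(bg) < 2) stop("Need at least 2 background nodes.", call. = FALSE)
  mr <- traction_magnitudes(fr)
  patches <- sort(unique(assignment[assignment > 0]))
  signal <- mean(purrr::map_dbl(patches, ~ mean(mr[assignment == .x])))
  noise <- if (background_std == "components") {
    comp <- c(fr[2 * which(bg) - 1], fr[2 * which(bg)])
    stats::sd(comp)
  } else {
    stats::sd(mr[bg])
  }
  if (noise == 0) return(Inf)
  signal / noise
}

#' Deviation of the traction maximum at adhesions (DMA)
#'
#' Per-patch relative error of the maximal traction magnitude, averaged
#' over patches; 0 means local maxima are recovered exactly,
#' positive/negative means over-/underestimation of the peaks.
#'
#' @inheritParams dtma
#' @export
dma <- function(recon, real, assignment) {
  fr <- as_traction_vector(recon)
  ft <- as_traction_vector(real)
  check_assignment(assignment, fr)
  vals <- patch_stats(traction_magnitudes(fr), traction_magnitudes(ft),
                      assignment, max)
  mean(vals)
}

#' All four metrics as a one-row report
#'
#' @inheritParams snr
#' @inheritParams dtma
#' @return A one-row tibble with columns `dtma`, `dtmb`, `snr`, `dma`.
#' @export
error_report <- function(recon, real, assignment,
                         background_std = c("components", "magnitude")) {
  tibble::tibble(
    dtma = dtma(recon, real, assignment),
    dtmb = dtmb(recon, real, assignment),
    snr = snr(recon, assignment, background_std),
    dma = dma(recon, real, assignment)
  )
}
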