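#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a penalized reconstruction
#'
#' @param x A `tfm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per traction node: `x`, `y`, `tx`, `ty`,
#'   `magnitude` (positions only when the fit carries its grid).
#' @export
tidy.tfm_fit <- function(x, ...) {
  f <- x$traction
  if (!is.null(x$nodes)) {
    out <- traction_tibble(f, x$nodes)
  } else {
    n <- length(f) / 2
    out <- tibble::tibble(x = NA_real_, y = NA_real_,
                          tx = f[seq(1, 2 * n, 2)],
                          ty = f[seq(2, 2 * n, 2)])
  }
  out$magnitude <- sqrt(out$tx^2 + out$ty^2)
  out
}

#' @rdname tidy.tfm_fit
#' @export
glance.tfm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, lambda1 = x$lambda1, lambda2 = x$lambda2,
    residual_norm = x$residual_norm,
    penalty_l1 = x$penalty_l1, penalty_l2 = x$penalty_l2,
    iterations = x$iterations, converged = x$converged,
    objective = x$objective
  )
}

#' Tidy an evidence-maximization result
#'
#' @param x A `tfm_evidence` from [bl2()] or [abl2()].
#' @param ... Unused.
#' @return The sampled evidence surface as a tibble (`alpha`, `beta`,
#'   `log_evidence`).
#' @export
tidy.tfm_evidence <- function(x, ...) {
  x$surface
}

#' @rdname tidy.tfm_evidence
#' @export
glance.tfm_evidence <- function(x, ...) {
  tibble::tibble(
    method = x$method, alpha = x$alpha, beta = x$beta,
    lambda = x$lambda, log_evidence = x$log_evidence,
    boundary = x$boundary
  )
}

#' MAP traction of an evidence result as a tidy table
#'
#' @param x A `tfm_evidence`.
#' @return Tibble `x`, `y`, `tx`, `ty`, `magnitude` (Pa).
#' @export
map_traction_table <- function(x) {
  stopifnot(inherits(x, "tfm_evidence"))
  grid <- x$problem$grid
  if (is.null(grid)) {
    stop("Evidence result carries no grid (plain-matrix problem).",
         call. = FALSE)
  }
  out <- traction_tibble(x$f_map, grid)
  out$magnitude <- sqrt(out$tx^2 + out$ty^2)
  out
}

#' @export
tidy.tfm_lcurve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.tfm_lcurve <- function(x, ...) {
  tibble::tibble(corner_lambda = attr(x, "corner_lambda"),
                 corner_method = attr(x, "corner_method"),
                 n_candidates = length(attr(x, "candidates")))
}
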