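#' Discrete displacement field
#'
#' A set of m sample positions with 2-D displacement vectors, the standard
#' tabular exchange format of this package (one row per fiducial marker).
#'
#' @param data A data frame with numeric columns `x`, `y`, `ux`, `uy`.
#' @param unit Length unit of both positions and displacements, `"um"` or
#'   `"pix"`.
#' @param pixel_size Pixel size in micrometres per pixel, used when
#'   converting between the two unit systems.
#'
#' @return A `displacement_field` tibble with attributes `unit` and
#'   `pixel_size`.
#' @export
displacement_field <- function(data, unit = c("um", "pix"), pixel_size = 0.1) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data))
  need <- c("x", "y", "ux", "uy")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns x, y, ux, uy.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)[need]
  if (nrow(data) == 0) stop("Empty displacement field.", call. = FALSE)
  ok <- vapply(data, function(col) is.numeric(col) && all(is.finite(col)),
               logical(1))
  if (!all(ok)) {
    stop("All positions and displacements must be finite numerics.",
         call. = FALSE)
  }
  structure(data, unit = unit, pixel_size = pixel_size,
            class = c("displacement_field", class(data)))
}

field_unit <- function(field) attr(field, "unit")

is_displacement_field <- function(x) inherits(x, "displacement_field")

#' Convert a displacement field between micrometre and pixel units
#'
#' Positions and displacement components are rescaled together, so an
#' inverse noise variance beta expressed in Pix^-2 is well defined after
#' conversion to pixel units.
#'
#' @param field A [displacement_field()].
#' @param unit Target unit, `"um"` or `"pix"`.
#' @param pixel_size Micrometres per pixel; defaults to the value recorded
#'   on the field.
#' @return A converted `displacement_field`.
#' @export
convert_units <- function(field, unit = c("um", "pix"), pixel_size = NULL) {
  unit <- match.arg(unit)
  stopifnot(is_displacement_field(field))
  ps <- pixel_size %||% attr(field, "pixel_size")
  from <- field_unit(field)
  if (from == unit) return(field)
  fac <- if (from == "um" && unit == "pix") 1 / ps else ps
  out <- tibble::as_tibble(field)
  out$x <- out$x * fac
  out$y <- out$y * fac
  out$ux <- out$ux * fac
  out$uy <- out$uy * fac
  displacement_field(out, unit = unit, pixel_size = ps)
}

# Stack a displacement field into the interleaved 2m vector
# (u1x, u1y, u2x, u2y, ...) used by the forward operator.
as_displacement_vector <- function(u) {
  if (is_displacement_field(u)) {
    as.vector(rbind(u$ux, u$uy))
  } else if (is.numeric(u)) {
    as.vector(u)
  } else {
    stop("Expected a displacement_field or a numeric vector.", call. = FALSE)
  }
}

# Interleaved 2n traction vector -> tibble on grid nodes.
traction_tibble <- function(f, nodes) {
  n <- length(f) / 2
  stopifnot(n == nrow(nodes))
  tibble::tibble(x = nodes$x, y = nodes$y,
                 tx = f[seq(1, 2 * n, by = 2)],
                 ty = f[seq(2, 2 * n, by = 2)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
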