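#' Regular traction discretization grid
#'
#' Node-centered regular grid on which the traction field is discretized
#' with pyramidal (bilinear tensor-product) shape functions. The origin sits
#' at the lower-left node and lengths are in a consistent user-chosen unit
#' (`"um"` or `"pix"`).
#'
#' @param extent Length-1 or length-2 numeric: domain size per axis. Nodes
#'   span `[0, extent]` inclusive.
#' @param spacing Mesh constant (node spacing), positive, identical in both
#'   axes. `extent` must be an integer multiple of `spacing`.
#' @param unit Length unit tag, `"um"` or `"pix"`.
#'
#' @return A `traction_grid`: a tibble with columns `x`, `y` (node
#'   positions, fastest along x) and attributes `spacing`, `nx`, `ny`,
#'   `unit`.
#' @examples
#' traction_grid(25, 0.5, unit = "um")
#' @export
traction_grid <- function(extent, spacing, unit = c("um", "pix")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(extent), length(extent) %in% c(1, 2),
            all(extent > 0), is.numeric(spacing), length(spacing) == 1,
            spacing > 0)
  extent <- rep(extent, length.out = 2)
  n <- extent / spacing
  if (any(abs(n - round(n)) > 1e-8)) {
    stop("`extent` must be an integer multiple of `spacing`.", call. = FALSE)
  }
  nx <- as.integer(round(n[1])) + 1L
  ny <- as.integer(round(n[2])) + 1L
  if (nx < 2 || ny < 2) {
    stop("Degenerate grid: need at least 2 nodes per axis.", call. = FALSE)
  }
  nodes <- tidyr::expand_grid(y = (seq_len(ny) - 1) * spacing,
                              x = (seq_len(nx) - 1) * spacing)
  nodes <- dplyr::select(nodes, "x", "y")
  structure(nodes,
            spacing = spacing, nx = nx, ny = ny, unit = unit,
            class = c("traction_grid", class(nodes)))
}

grid_spacing <- function(grid) attr(grid, "spacing")
grid_dims <- function(grid) c(attr(grid, "nx"), attr(grid, "ny"))
grid_unit <- function(grid) attr(grid, "unit")
n_nodes <- function(grid) nrow(grid)

is_traction_grid <- function(x) inherits(x, "traction_grid")

assert_regular_grid <- function(grid) {
  if (!is_traction_grid(grid)) {
    stop("Expected a `traction_grid` (regular lattice).", call. = FALSE)
  }
  invisible(grid)
}

#' Convert a traction grid between length units
#'
#' @param grid A [traction_grid()].
#' @param unit Target unit, `"um"` or `"pix"`.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return A rescaled `traction_grid`.
#' @export
convert_grid_units <- function(grid, unit = c("um", "pix"), pixel_size = 0.1) {
  unit <- match.arg(unit)
  assert_regular_grid(grid)
  from <- grid_unit(grid)
  if (from == unit) return(grid)
  fac <- if (from == "um" && unit == "pix") 1 / pixel_size else pixel_size
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  out <- tibble::tibble(x = grid$x * fac, y = grid$y * fac)
  structure(out,
            spacing = grid_spacing(grid) * fac, nx = nx, ny = ny, unit = unit,
            class = c("traction_grid", class(out)))
}
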