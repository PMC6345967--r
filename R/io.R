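#' Read a displacement table
#'
#' Parses 4-column numeric tabular text (`x y ux uy`), whitespace- or
#' comma-delimited (sniffed from the first data line), with `#` comment
#' lines. Header comments of the form `# key: value` are honoured for
#' `unit` and `pixel_size`; explicit arguments override them. Ragged rows,
#' non-numeric cells and NaN values are rejected with their line number.
#'
#' @param path File path.
#' @param unit Optional unit override (`"um"` or `"pix"`).
#' @param pixel_size Optional pixel-size override (um/Pix).
#' @return A [displacement_field()].
#' @export
read_displacements <- function(path, unit = NULL, pixel_size = NULL) {
  parsed <- parse_table(path, n_cols = 4)
  meta <- parsed$meta
  unit <- unit %||% meta$unit %||% "um"
  pixel_size <- pixel_size %||% as.numeric(meta$pixel_size %||% 0.1)
  df <- stats::setNames(parsed$data, c("x", "y", "ux", "uy"))
  displacement_field(df, unit = match.arg(unit, c("um", "pix")),
                     pixel_size = pixel_size)
}

parse_table <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  data_rows <- list()
  data_lines <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- regmatches(ln,
                       regexec("^#\\s*([A-Za-z][A-Za-z0-9_.]*)\\s*:\\s*(.+)$",
                               ln))[[1]]
      if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
      next
    }
    data_lines <- c(data_lines, i)
    data_rows[[length(data_rows) + 1L]] <- ln
  }
  if (length(data_rows) == 0) {
    stop("Empty input: no data rows in '", path, "'.", call. = FALSE)
  }
  delim <- if (grepl(",", data_rows[[1]])) "," else "[[:space:]]+"
  mat <- matrix(NA_real_, length(data_rows), n_cols)
  for (k in seq_along(data_rows)) {
    cells <- strsplit(data_rows[[k]], delim)[[1]]
    cells <- cells[cells != ""]
    if (length(cells) != n_cols) {
      stop("Line ", data_lines[k], ": expected ", n_cols,
           " columns, found ", length(cells), ".", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop("Line ", data_lines[k], ": non-numeric or non-finite cell.",
           call. = FALSE)
    }
    mat[k, ] <- vals
  }
  list(data = as.data.frame(mat), meta = meta)
}

#' Write a displacement field
#'
#' Four-column text (`x y ux uy`) with a commented header recording the
#' unit, pixel size and any seeds attached to the field. Values keep 15
#' significant digits, so a write/read round trip is lossless at 12
#' digits.
#'
#' @param field A [displacement_field()].
#' @param path Output path.
#' @param extra_header Named list of further `# key: value` entries.
#' @return `path`, invisibly.
#' @export
write_displacements <- function(field, path, extra_header = list()) {
  stopifnot(is_displacement_field(field))
  hdr <- c(unit = field_unit(field),
           pixel_size = attr(field, "pixel_size"),
           noise_sigma = attr(field, "noise_sigma"),
           noise_beta = attr(field, "noise_beta"),
           noise_seed = attr(field, "noise_seed"),
           sampling_seed = attr(field, "sampling_seed"))
  hdr <- c(hdr[!vapply(hdr, is.null, logical(1))], unlist(extra_header))
  write_tabular(cbind(field$x, field$y, field$ux, field$uy),
                c("x", "y", "ux", "uy"), hdr, path)
  invisible(path)
}

write_tabular <- function(mat, col_names, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(header)) {
    writeLines(paste0("# ", names(header)[k], ": ", header[[k]]), con)
  }
  writeLines(paste0("# columns: ", paste(col_names, collapse = " ")), con)
  apply(mat, 1, function(row) {
    writeLines(paste(sprintf("%.15g", row), collapse = " "), con)
  })
  invisible(path)
}

#' Write a reconstructed traction field
#'
#' Four-column text (`x y tx ty`, traction in Pa) with a metadata header
#' recording the method and the regularization parameters actually used
#' (lambda values, or alpha/beta/lambda for the Bayesian solvers).
#'
#' @param fit A `tfm_fit` or `tfm_evidence` result.
#' @param path Output path.
#' @param grid Node grid; taken from the fit when available.
#' @param extra_header Named list of further header entries.
#' @return `path`, invisibly.
#' @export
write_traction <- function(fit, path, grid = NULL, extra_header = list()) {
  if (inherits(fit, "tfm_evidence")) {
    f <- fit$f_map
    grid <- grid %||% fit$problem$grid
    hdr <- c(method = fit$method, alpha = fit$alpha, beta = fit$beta,
             lambda = fit$lambda, unit_traction = "Pa")
  } else if (inherits(fit, "tfm_fit")) {
    f <- fit$traction
    grid <- grid %||% fit$nodes
    hdr <- c(method = fit$method, lambda1 = fit$lambda1,
             lambda2 = fit$lambda2, unit_traction = "Pa")
  } else {
    stop("`fit` must be a tfm_fit or tfm_evidence.", call. = FALSE)
  }
  if (is.null(grid)) stop("No node grid available for output.",
                          call. = FALSE)
  hdr <- c(hdr, unlist(extra_header))
  tt <- traction_tibble(f, grid)
  write_tabular(cbind(tt$x, tt$y, tt$tx, tt$ty),
                c("x", "y", "tx", "ty"), hdr, path)
  invisible(path)
}

#' Read a traction table written by [write_traction()]
#'
#' @param path File path.
#' @return A tibble (`x`, `y`, `tx`, `ty`) with the parsed header in
#'   attribute `meta`.
#' @export
read_traction <- function(path) {
  parsed <- parse_table(path, n_cols = 4)
  out <- tibble::as_tibble(stats::setNames(parsed$data,
                                           c("x", "y", "tx", "ty")))
  attr(out, "meta") <- parsed$meta
  out
}

#' Scene serialization
#'
#' Writes/reads a spot scene as a structured YAML text record (domain,
#' substrate constants, seed, and per-spot centres, radii and traction
#' vectors).
#'
#' @param scene A spot scene.
#' @param path File path.
#' @return `write_scene` returns `path` invisibly; `read_scene` the
#'   restored scene.
#' @export
write_scene <- function(scene, path) {
  stopifnot(is_spot_scene(scene))
  sub <- scene_substrate(scene)
  rec <- list(
    domain = as.numeric(scene_domain(scene)),
    youngs_modulus = sub$youngs_modulus,
    poisson_ratio = sub$poisson_ratio,
    seed = attr(scene, "seed"),
    variant = attr(scene, "variant"),
    spots = purrr::pmap(scene[c("x", "y", "radius", "tx", "ty")], list)
  )
  writeLines(yaml::as.yaml(rec, precision = 15), path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  rec <- yaml::read_yaml(path)
  spots <- dplyr::bind_rows(lapply(rec$spots, tibble::as_tibble))
  spots$magnitude <- sqrt(spots$tx^2 + spots$ty^2)
  structure(spots,
            domain = as.numeric(rec$domain),
            substrate = elastic_substrate(rec$youngs_modulus,
                                          rec$poisson_ratio),
            seed = rec$seed %||% NA_integer_,
            variant = rec$variant %||% "custom",
            class = c("spot_scene", class(spots)))
}
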