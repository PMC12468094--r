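# Plain-text elevation-grid dialect:
#   # spacing_mm=<v>
#   # diameter_mm=<v>
#   # units=mm
#   x_mm,y_mm,z_ant_mm,z_post_mm
# one row per lattice node (y outer, x inner), 6 decimals, masked points NaN.

#' Write a topography grid to the plain-text CSV dialect
#'
#' @param grid a `topography_grid`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "topography_grid"))
  n <- length(grid$x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spacing_mm=%.6f", grid$spacing),
               sprintf("# diameter_mm=%.6f", grid$diameter),
               "# units=mm",
               "x_mm,y_mm,z_ant_mm,z_post_mm"), con)
  X <- matrix(grid$x, n, n)
  Y <- matrix(grid$y, n, n, byrow = TRUE)
  za <- grid$z_ant; zp <- grid$z_post
  za[!grid$mask] <- NA_real_
  zp[!grid$mask] <- NA_real_
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.6f", v), "NaN")
  # y outer, x inner
  ord <- order(rep(grid$y, each = n), rep(grid$x, n))
  lines <- paste(fmt(as.vector(X)), fmt(as.vector(Y)),
                 fmt(as.vector(za)), fmt(as.vector(zp)), sep = ",")[ord]
  writeLines(lines, con)
  invisible(path)
}

#' Read a topography grid from the plain-text CSV dialect
#'
#' Errors (with the offending line number) on missing header keys, unit
#' mismatch, garbled rows or non-rectangular lattices. Pachymetry is
#' recomputed from the two elevations; the validity mask is taken from the
#' NaN sentinels.
#'
#' @param path input file path
#' @return a `topography_grid`
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_cxl(sprintf("line %d: malformed header '%s'", i, lines[i]),
               "cxl_parse_error")
    }
    hdr[[trimws(parts[1])]] <- trimws(parts[2])
    i <- i + 1L
  }
  for (key in c("spacing_mm", "diameter_mm", "units")) {
    if (is.null(hdr[[key]])) {
      stop_cxl(sprintf("line %d: missing required header key '%s'", i, key),
               "cxl_parse_error")
    }
  }
  if (hdr$units != "mm") {
    stop_cxl(sprintf("unit mismatch: expected 'mm', got '%s'", hdr$units),
             "cxl_parse_error")
  }
  if (i > length(lines) || lines[i] != "x_mm,y_mm,z_ant_mm,z_post_mm") {
    stop_cxl(sprintf("line %d: expected column header 'x_mm,y_mm,z_ant_mm,z_post_mm'", i),
             "cxl_parse_error")
  }
  spacing <- as.numeric(hdr$spacing_mm)
  diameter <- as.numeric(hdr$diameter_mm)
  if (!is.finite(spacing) || spacing <= 0 || !is.finite(diameter)) {
    stop_cxl("invalid spacing_mm/diameter_mm header values", "cxl_parse_error")
  }
  body <- lines[(i + 1L):length(lines)]
  body_ln <- (i + 1L):length(lines)
  keep <- nzchar(body)
  body <- body[keep]; body_ln <- body_ln[keep]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop_cxl(sprintf("line %d: expected 4 comma-separated fields, got %d",
                     body_ln[bad], nf[bad]), "cxl_parse_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 4, byrow = TRUE)
  xy_bad <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]))
  if (length(xy_bad)) {
    stop_cxl(sprintf("line %d: non-numeric lattice coordinates", body_ln[xy_bad[1]]),
             "cxl_parse_error")
  }
  xs <- sort(unique(m[, 1]))
  ys <- sort(unique(m[, 2]))
  nx <- length(xs); ny <- length(ys)
  ix <- as.integer(round((m[, 1] - xs[1]) / spacing)) + 1L
  iy <- as.integer(round((m[, 2] - ys[1]) / spacing)) + 1L
  if (nrow(m) != nx * ny || anyDuplicated(ix + nx * (iy - 1L)) ||
      max(ix) != nx || max(iy) != ny) {
    stop_cxl("non-rectangular grid: lattice rows do not form a full nx-by-ny product",
             "cxl_parse_error")
  }
  z_ant <- matrix(NA_real_, nx, ny)
  z_post <- matrix(NA_real_, nx, ny)
  z_ant[cbind(ix, iy)] <- m[, 3]
  z_post[cbind(ix, iy)] <- m[, 4]
  mask <- is.finite(z_ant) & is.finite(z_post)
  structure(list(x = xs, y = ys, z_ant = z_ant, z_post = z_post,
                 pachy = (z_post - z_ant) * 1000, mask = mask,
                 spacing = spacing, diameter = diameter, spec = NULL),
            class = "topography_grid")
}
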