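# Bicubic (Catmull-Rom) interpolation on the regular topography lattice.
# Used for mesh node placement and material-field evaluation; falls back to
# bilinear, then nearest-valid, where the 4x4 stencil touches masked points.

catmull_weights <- function(t) {
  cbind(0.5 * (-t + 2 * t^2 - t^3),
        0.5 * (2 - 5 * t^2 + 3 * t^3),
        0.5 * (t + 4 * t^2 - 3 * t^3),
        0.5 * (-t^2 + t^3))
}

#' Interpolate a topography grid at arbitrary lateral positions
#'
#' Bicubic interpolation of the anterior elevation, posterior elevation or
#' thickness of a [topography_grid] at scattered `(x, y)` points (mm).
#'
#' @param grid a `topography_grid`
#' @param x,y query coordinates (mm)
#' @param what one of `"ant"`, `"post"`, `"th"` (thickness, mm)
#' @return numeric vector of interpolated values (mm)
#' @export
grid_interp <- function(grid, x, y, what = c("ant", "post", "th")) {
  what <- match.arg(what)
  Z <- switch(what, ant = grid$z_ant, post = grid$z_post,
              th = grid$z_post - grid$z_ant)
  gx <- grid$x; gy <- grid$y
  h <- grid$spacing
  nx <- length(gx); ny <- length(gy)
  ix <- floor((x - gx[1]) / h) + 1L
  iy <- floor((y - gy[1]) / h) + 1L
  ix <- pmin(pmax(ix, 2L), nx - 2L)
  iy <- pmin(pmax(iy, 2L), ny - 2L)
  tx <- (x - gx[ix]) / h
  ty <- (y - gy[iy]) / h
  wx <- catmull_weights(tx)
  wy <- catmull_weights(ty)
  out <- numeric(length(x))
  for (a in 1:4) {
    rowsum <- numeric(length(x))
    for (b in 1:4) {
      v <- Z[cbind(ix + a - 2L, iy + b - 2L)]
      rowsum <- rowsum + wy[, b] * v
    }
    out <- out + wx[, a] * rowsum
  }
  bad <- !is.finite(out)
  if (any(bad)) {
    # bilinear on the inner 2x2 stencil
    for (q in which(bad)) {
      i <- ix[q]; j <- iy[q]
      v <- Z[i:(i + 1), j:(j + 1)]
      if (all(is.finite(v))) {
        out[q] <- (1 - tx[q]) * ((1 - ty[q]) * v[1, 1] + ty[q] * v[1, 2]) +
          tx[q] * ((1 - ty[q]) * v[2, 1] + ty[q] * v[2, 2])
      }
    }
    bad <- !is.finite(out)
  }
  if (any(bad)) {
    valid <- which(is.finite(Z), arr.ind = TRUE)
    vx <- gx[valid[, 1]]; vy <- gy[valid[, 2]]
    vz <- Z[valid]
    for (q in which(bad)) {
      out[q] <- vz[which.min((vx - x[q])^2 + (vy - y[q])^2)]
    }
  }
  out
}

# Lateral gradient of a surface by central differences of the interpolant.
grid_gradient <- function(grid, x, y, what = "ant", h = 1e-3) {
  list(zx = (grid_interp(grid, x + h, y, what) -
               grid_interp(grid, x - h, y, what)) / (2 * h),
       zy = (grid_interp(grid, x, y + h, what) -
               grid_interp(grid, x, y - h, what)) / (2 * h))
}
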