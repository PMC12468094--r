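# Anterior-surface keratometry: tangential curvature from local best-fitting
# spheres, Kmax-t / KmaxMean3, biconic fitting with the derived clinical
# indices, minimum pachymetry, and percentile-based keratoconus cone
# detection.

as_surface_points <- function(surface_points) {
  if (inherits(surface_points, "topography_grid")) {
    pts <- grid_points(surface_points, "ant")
    attr(pts, "lattice") <- list(x = surface_points$x, y = surface_points$y,
                                 spacing = surface_points$spacing,
                                 idx = which(surface_points$mask))
    return(pts)
  }
  pts <- as.matrix(surface_points)
  if (ncol(pts) != 3) stop("surface points must be an n x 3 matrix or a topography_grid")
  pts
}

#' Tangential curvature map from local sphere fits
#'
#' For every surface node, fits a least-squares sphere through all points
#' within `neighborhood_radius` (lateral distance); if fewer than `min_pts`
#' points fall inside, the neighborhood grows to the `k_fallback` nearest
#' nodes. The tangential curvature is `K_tg = (1.3375 - 1) / R` with `R` in
#' metres, i.e. `337.5 / R[mm]` dioptres.
#'
#' @param surface_points a `topography_grid` (anterior surface) or an
#'   n x 3 point matrix (mm)
#' @param neighborhood_radius lateral neighborhood radius (mm); the study's
#'   "120 um region" read as a 0.12 mm radius
#' @param min_pts minimum neighborhood size before the k-nearest fallback
#' @param k_fallback number of nearest nodes used by the fallback
#' @return a `curvature_map`: data frame with `x`, `y`, `z`, `R_mm`, `K_tg`
#'   (D) and `valid`; lattice metadata is carried over when the input is a
#'   grid
#' @export
tangential_curvature <- function(surface_points, neighborhood_radius = 0.12,
                                 min_pts = 6, k_fallback = 8) {
  pts <- as_surface_points(surface_points)
  lattice <- attr(pts, "lattice")
  R <- as.numeric(local_sphere_radius(pts, neighborhood_radius,
                                      as.integer(min_pts),
                                      as.integer(k_fallback)))
  K <- (KERATOMETRIC_INDEX_TANGENTIAL - 1) * 1000 / R
  map <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    R_mm = R, K_tg = K, valid = is.finite(K) & K > 0)
  class(map) <- c("curvature_map", "data.frame")
  attr(map, "lattice") <- lattice
  map
}

#' Maximum tangential curvature and its 3 mm zonal mean
#'
#' `kmax_t` is the maximum valid tangential curvature; `kmaxmean3` the
#' unweighted mean curvature over valid nodes within a disc (default 3 mm
#' diameter) centred at the curvature maximum.
#'
#' @param map a `curvature_map`
#' @param zone_diameter averaging zone diameter (mm)
#' @return list with `kmax_t` (D), `location` (x, y), `kmaxmean3` (D)
#' @export
kmax_metrics <- function(map, zone_diameter = 3) {
  ok <- which(map$valid)
  if (!length(ok)) stop_cxl("curvature map has no valid nodes", "cxl_metric_error")
  imax <- ok[which.max(map$K_tg[ok])]
  cx <- map$x[imax]; cy <- map$y[imax]
  inzone <- ok[(map$x[ok] - cx)^2 + (map$y[ok] - cy)^2 <= (zone_diameter / 2)^2]
  list(kmax_t = map$K_tg[imax], location = c(x = cx, y = cy),
       kmaxmean3 = mean(map$K_tg[inzone]))
}

#' Minimum pachymetry
#'
#' Minimum corneal thickness over valid lattice nodes. Ties are broken by
#' smallest lateral radius, then lexicographically by (x, y).
#'
#' @param grid a `topography_grid`
#' @return list with `value` (um) and `location` (x, y in mm)
#' @export
min_pachymetry <- function(grid) {
  stopifnot(inherits(grid, "topography_grid"))
  idx <- which(grid$mask)
  if (!length(idx)) stop_cxl("all grid points are masked", "cxl_metric_error")
  n <- length(grid$x)
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  p <- grid$pachy[idx]
  x <- grid$x[i]; y <- grid$y[j]
  ord <- order(p, x^2 + y^2, x, y)
  k <- ord[1]
  list(value = p[k], location = c(x = x[k], y = y[k]))
}

# --- biconic fitting --------------------------------------------------------

biconic_model <- function(par, x, y) {
  # par: Rx, Ry, theta(rad), Qx, Qy, x0, y0, z0
  u <- (x - par[6]) * cos(par[3]) + (y - par[7]) * sin(par[3])
  v <- -(x - par[6]) * sin(par[3]) + (y - par[7]) * cos(par[3])
  cx <- 1 / par[1]; cy <- 1 / par[2]
  rad <- 1 - (1 + par[4]) * cx^2 * u^2 - (1 + par[5]) * cy^2 * v^2
  rad[rad < 1e-8] <- 1e-8
  par[8] + (cx * u^2 + cy * v^2) / (1 + sqrt(rad))
}

biconic_init <- function(x, y, z) {
  # paraboloid least squares: z = b0 + b1 x + b2 y + a11 x^2/2 + a12 xy + a22 y^2/2
  A <- cbind(1, x, y, x^2 / 2, x * y, y^2 / 2)
  beta <- qr.solve(A, z)
  M <- matrix(c(beta[4], beta[5], beta[5], beta[6]), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  kap <- pmax(ev$values, 1e-3)           # principal curvatures (1/mm)
  # eigenvector of the SMALLER curvature = flat meridian
  vflat <- ev$vectors[, which.min(ev$values)]
  theta <- atan2(vflat[2], vflat[1]) %% pi
  # vertex: gradient zero
  off <- tryCatch(-solve(M, beta[2:3]), error = function(e) c(0, 0))
  off <- pmin(pmax(off, -2), 2)
  z0 <- beta[1] + sum(beta[2:3] * off) +
    0.5 * (M[1, 1] * off[1]^2 + 2 * M[1, 2] * off[1] * off[2] + M[2, 2] * off[2]^2)
  c(1 / min(kap), 1 / max(kap), theta, -0.2, -0.2, off[1], off[2], z0)
}

#' Fit a biconic surface and derive clinical keratometry indices
#'
#' Nonlinear least squares of a rotated biconic sag over points within
#' `fit_diameter` (default 8 mm). Derived indices use the keratometric index
#' 1.376: `K = 376 / R[mm]`, `sphere = K_flat`, `cylinder = K_steep - K_flat`
#' (non-negative by the `R_steep < R_flat` ordering), and
#' `spherical_equivalent = sphere + cylinder / 2`. The astigmatism `axis` is
#' the steep meridian angle in degrees `[0, 180)`.
#'
#' @inheritParams tangential_curvature
#' @param fit_diameter diameter of the fitted area (mm)
#' @param max_restarts perturbed restarts on non-convergence
#' @return object of class `biconic_fit`
#' @export
fit_biconic <- function(surface_points, fit_diameter = 8, max_restarts = 5) {
  pts <- as_surface_points(surface_points)
  rho2 <- pts[, 1]^2 + pts[, 2]^2
  sel <- rho2 <= (fit_diameter / 2)^2
  if (max(sqrt(rho2)) < 0.45 * fit_diameter || sum(sel) < 50) {
    stop_cxl("surface points do not cover the biconic fit diameter",
             "cxl_metric_error")
  }
  x <- pts[sel, 1]; y <- pts[sel, 2]; z <- pts[sel, 3]
  obj <- function(par) mean((biconic_model(par, x, y) - z)^2)
  p0 <- biconic_init(x, y, z)
  lower <- c(4, 4, -2 * pi, -1.5, -1.5, -2, -2, -5)
  upper <- c(25, 25, 2 * pi, 1, 1, 2, 2, 5)
  p0 <- pmin(pmax(p0, lower), upper)
  best <- NULL
  tries <- list(p0)
  for (k in seq_len(max_restarts)) {
    pk <- p0
    pk[3] <- (p0[3] + k * pi / (max_restarts + 1)) %% pi
    pk[4:5] <- p0[4:5] + 0.15 * (-1)^k
    tries[[k + 1]] <- pk
  }
  for (pk in tries) {
    fit <- tryCatch(nlminb(pk, obj, lower = lower, upper = upper,
                           control = list(iter.max = 500, eval.max = 1000)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (best$objective < (2e-5)^2) break  # sub-20 nm mean square: exact data
  }
  if (is.null(best)) {
    stop_cxl("biconic fit failed to converge after restarts", "cxl_metric_error")
  }
  par <- unname(best$par)
  rms_um <- sqrt(best$objective) * 1000
  ru <- par[1]; rv <- par[2]; theta <- par[3] %% pi
  if (ru >= rv) {
    r_flat <- ru; r_steep <- rv
    q_flat <- par[4]; q_steep <- par[5]
    axis_steep <- (theta * 180 / pi + 90) %% 180
  } else {
    r_flat <- rv; r_steep <- ru
    q_flat <- par[5]; q_steep <- par[4]
    axis_steep <- (theta * 180 / pi) %% 180
  }
  kcoef <- (KERATOMETRIC_INDEX_BICONIC - 1) * 1000
  k_steep <- kcoef / r_steep
  k_flat <- kcoef / r_flat
  structure(list(
    R_steep = r_steep, R_flat = r_flat, axis = axis_steep,
    Q_steep = q_steep, Q_flat = q_flat,
    center_offset = c(x = par[6], y = par[7]), z0 = par[8],
    K_steep = k_steep, K_flat = k_flat,
    sphere = k_flat, cylinder = k_steep - k_flat,
    spherical_equivalent = k_flat + (k_steep - k_flat) / 2,
    rms_residual_um = rms_um, converged = best$convergence == 0,
    n_points = length(x)), class = "biconic_fit")
}

#' @export
print.biconic_fit <- function(x, ...) {
  cat(sprintf("biconic fit: R_steep %.3f mm, R_flat %.3f mm, axis %.1f deg\n",
              x$R_steep, x$R_flat, x$axis))
  cat(sprintf("  sphere %.2f D, cylinder %.2f D, SE %.2f D (rms %.2f um, n=%d)\n",
              x$sphere, x$cylinder, x$spherical_equivalent,
              x$rms_residual_um, x$n_points))
  invisible(x)
}

# --- cone detection ---------------------------------------------------------

#' Detect the keratoconus cone region
#'
#' Within the central `region_diameter` (8 mm) of the curvature map, the cone
#' is the set of nodes whose tangential curvature strictly exceeds the
#' 67.5th percentile (linear-interpolation definition) of the central
#' curvature distribution. The cone centre is the curvature argmax among
#' members; each member receives a normalized boundary distance in [0, 1]
#' (distance from the centre divided by the distance to the first non-member
#' along the same ray).
#'
#' Requires a lattice-backed map (one computed from a `topography_grid`).
#'
#' @param map a `curvature_map` with lattice metadata
#' @param region_diameter detection region diameter (mm)
#' @param percentile percentile threshold (fraction)
#' @param ntheta angular resolution of the boundary-distance map
#' @return object of class `cone_region`
#' @export
detect_cone <- function(map, region_diameter = 8, percentile = 0.675,
                        ntheta = 360) {
  lattice <- attr(map, "lattice")
  if (is.null(lattice)) {
    stop_cxl("detect_cone requires a lattice-backed curvature map", "cxl_metric_error")
  }
  rho2 <- map$x^2 + map$y^2
  central <- which(map$valid & rho2 <= (region_diameter / 2)^2)
  if (length(central) < 20) {
    stop_cxl("fewer than 20 valid nodes in the central detection region",
             "cxl_metric_error")
  }
  thr <- unname(quantile(map$K_tg[central], percentile, type = 7))
  # strict exceedance, with an absolute guard so that floating-point jitter
  # on a constant map does not fabricate members
  members <- central[map$K_tg[central] > thr + 1e-8]
  if (!length(members)) {
    stop_cxl("no node strictly exceeds the curvature percentile; treat cornea as KC-free",
             "cxl_empty_cone")
  }
  imax <- members[which.max(map$K_tg[members])]
  center <- c(x = map$x[imax], y = map$y[imax])

  # member indicator on the lattice
  nx <- length(lattice$x); ny <- length(lattice$y)
  member_mat <- matrix(FALSE, nx, ny)
  member_mat[lattice$idx[members]] <- TRUE
  h <- lattice$spacing
  step <- h / 2
  tmax <- region_diameter
  tgrid <- seq(step, tmax, by = step)
  thetas <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  edge <- numeric(ntheta)
  for (k in seq_len(ntheta)) {
    px <- center[1] + tgrid * cos(thetas[k])
    py <- center[2] + tgrid * sin(thetas[k])
    ii <- as.integer(round((px - lattice$x[1]) / h)) + 1L
    jj <- as.integer(round((py - lattice$y[1]) / h)) + 1L
    inside <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    memb <- logical(length(tgrid))
    memb[inside] <- member_mat[cbind(ii[inside], jj[inside])]
    first_out <- which(!memb)[1]
    edge[k] <- if (is.na(first_out)) tmax else tgrid[first_out]
  }
  edge_at <- function(theta) {
    t0 <- theta %% (2 * pi)
    pos <- t0 / (2 * pi) * ntheta
    k0 <- floor(pos) %% ntheta
    frac <- pos - floor(pos)
    (1 - frac) * edge[k0 + 1] + frac * edge[(k0 + 1) %% ntheta + 1]
  }
  d <- sqrt((map$x[members] - center[1])^2 + (map$y[members] - center[2])^2)
  th <- atan2(map$y[members] - center[2], map$x[members] - center[1])
  nd <- pmin(pmax(d / vapply(th, edge_at, 0), 0), 1)
  structure(list(member_idx = members, center = center, threshold = thr,
                 normdist = nd, edge_theta = thetas, edge_dist = edge,
                 fraction = length(members) / length(central),
                 region_diameter = region_diameter,
                 lattice_members = lattice$idx[members],
                 lattice_dim = c(nx, ny)),
            class = "cone_region")
}

#' @export
print.cone_region <- function(x, ...) {
  cat(sprintf("cone_region: %d members (%.1f%% of central zone), centre (%.2f, %.2f) mm, threshold %.2f D\n",
              length(x$member_idx), 100 * x$fraction, x$center[1], x$center[2],
              x$threshold))
  invisible(x)
}

# Normalized boundary distance of arbitrary lateral points w.r.t. a cone
# region; >= 1 means outside the (star-shaped) cone.
cone_normdist <- function(cone, x, y) {
  dx <- x - cone$center[1]; dy <- y - cone$center[2]
  d <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  ntheta <- length(cone$edge_theta)
  pos <- th / (2 * pi) * ntheta
  k0 <- floor(pos) %% ntheta
  frac <- pos - floor(pos)
  ed <- (1 - frac) * cone$edge_dist[k0 + 1] +
    frac * cone$edge_dist[(k0 + 1) %% ntheta + 1]
  unname(pmin(d / ed, 1))
}
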