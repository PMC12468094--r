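# Synthetic keratoconic topographies: biconic base surface plus a localized
# cone (anterior protrusion with co-located stromal thinning), emulating the
# clinical population this pipeline targets (Kmax-t ~50-57 D, minimum
# pachymetry ~460 um).

#' Specification of a synthetic (keratoconic) cornea
#'
#' Describes a biconic anterior surface with an optional localized cone:
#' a Gaussian anterior protrusion of height `cone_amplitude` (mm) and width
#' `cone_sigma` (mm) centred at `cone_center`, with co-located stromal
#' thinning `cone_thinning` (um, same lateral profile). The posterior surface
#' is offset from the anterior along z by the local thickness.
#'
#' @param r_flat,r_steep apical radii of the flat/steep meridians (mm),
#'   `r_steep <= r_flat`
#' @param axis_flat meridian angle of the flat axis, degrees in `[0, 180)`
#' @param q_flat,q_steep asphericities (dimensionless)
#' @param cone_center cone location `(x, y)` in mm
#' @param cone_amplitude anterior protrusion height at the cone centre (mm),
#'   `>= 0`; 0 gives a pure biconic
#' @param cone_sigma Gaussian width of the cone (mm)
#' @param central_thickness thickness away from the cone (um)
#' @param cone_thinning thickness reduction at the cone centre (um),
#'   `< central_thickness`
#' @param grid_spacing lateral sampling (mm)
#' @param grid_diameter grid diameter (mm), `>= 9` so the treatment zone is
#'   covered
#' @param noise_sd measurement noise SD added to both elevations (um)
#' @param seed integer seed controlling the noise draw
#' @return object of class `cornea_spec`
#' @export
cornea_spec <- function(r_flat = 7.7, r_steep = 7.3, axis_flat = 0,
                        q_flat = -0.25, q_steep = -0.25,
                        cone_center = c(1.0, 0.5), cone_amplitude = 0.035,
                        cone_sigma = 1.2, central_thickness = 540,
                        cone_thinning = 78, grid_spacing = 0.1,
                        grid_diameter = 10, noise_sd = 0, seed = 1L) {
  spec <- structure(list(
    r_flat = r_flat, r_steep = r_steep, axis_flat = axis_flat,
    q_flat = q_flat, q_steep = q_steep,
    cone_center = as.numeric(cone_center), cone_amplitude = cone_amplitude,
    cone_sigma = cone_sigma, central_thickness = central_thickness,
    cone_thinning = cone_thinning, grid_spacing = grid_spacing,
    grid_diameter = grid_diameter, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "cornea_spec")
  validate_cornea_spec(spec)
  spec
}

#' @rdname cornea_spec
#' @param spec a `cornea_spec`
#' @export
validate_cornea_spec <- function(spec) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) {
      stop_cxl(sprintf("invalid cornea_spec: field '%s' %s", field, msg),
               "cxl_spec_error")
    }
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  chk(num1(spec$r_flat) && spec$r_flat > 0, "r_flat", "must be a positive number")
  chk(num1(spec$r_steep) && spec$r_steep > 0, "r_steep", "must be a positive number")
  chk(spec$r_steep <= spec$r_flat, "r_steep", "must satisfy r_steep <= r_flat")
  chk(num1(spec$axis_flat) && spec$axis_flat >= 0 && spec$axis_flat < 180,
      "axis_flat", "must lie in [0, 180)")
  chk(num1(spec$q_flat), "q_flat", "must be a number")
  chk(num1(spec$q_steep), "q_steep", "must be a number")
  chk(is.numeric(spec$cone_center) && length(spec$cone_center) == 2 &&
        all(is.finite(spec$cone_center)), "cone_center", "must be (x, y) in mm")
  chk(num1(spec$cone_amplitude) && spec$cone_amplitude >= 0,
      "cone_amplitude", "must be >= 0")
  chk(num1(spec$cone_sigma) && spec$cone_sigma > 0, "cone_sigma",
      "must be positive")
  chk(num1(spec$central_thickness) && spec$central_thickness > 0,
      "central_thickness", "must be positive (um)")
  chk(num1(spec$cone_thinning) && spec$cone_thinning >= 0 &&
        spec$cone_thinning < spec$central_thickness,
      "cone_thinning", "must be in [0, central_thickness)")
  chk(num1(spec$grid_spacing) && spec$grid_spacing > 0, "grid_spacing",
      "must be positive")
  chk(num1(spec$grid_diameter) && spec$grid_diameter >= 9, "grid_diameter",
      "must be >= 9 mm to cover the treatment zone")
  chk(num1(spec$noise_sd) && spec$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(length(spec$seed) == 1 && !is.na(spec$seed), "seed", "must be an integer")
  invisible(spec)
}

#' Sag of a rotated biconic surface
#'
#' `z = (cx u^2 + cy v^2) / (1 + sqrt(1 - (1+Qx) cx^2 u^2 - (1+Qy) cy^2 v^2))`
#' with `cx = 1/r_flat` along the flat meridian `u` (rotated by `axis_flat`)
#' and `cy = 1/r_steep` along `v`. z increases posteriorly, apex at origin.
#'
#' @param x,y lateral coordinates (mm)
#' @inheritParams cornea_spec
#' @return sag values (mm); NaN outside the surface's domain
#' @export
biconic_sag <- function(x, y, r_flat, r_steep, axis_flat = 0,
                        q_flat = 0, q_steep = 0) {
  th <- axis_flat * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  cx <- 1 / r_flat
  cy <- 1 / r_steep
  num <- cx * u^2 + cy * v^2
  rad <- 1 - (1 + q_flat) * cx^2 * u^2 - (1 + q_steep) * cy^2 * v^2
  rad[rad < 0] <- NA_real_
  num / (1 + sqrt(rad))
}

#' Generate a synthetic corneal topography
#'
#' Evaluates the spec's anterior surface (biconic minus the Gaussian cone
#' protrusion; z points posteriorly, so the cone steepens the surface at its
#' centre), offsets the posterior surface by the local thickness, optionally
#' adds seeded Gaussian elevation noise to both surfaces, and recomputes
#' pachymetry. Identical specs (and seeds) give bit-identical grids.
#'
#' @param spec a [cornea_spec()]
#' @return object of class `topography_grid` with fields `x`, `y` (lattice
#'   coordinates, mm), matrices `z_ant`, `z_post` (mm), `pachy` (um), logical
#'   `mask`, plus `spacing` and `diameter`
#' @export
generate_cornea <- function(spec) {
  validate_cornea_spec(spec)
  h <- spec$grid_spacing
  nh <- floor(spec$grid_diameter / 2 / h + 1e-9)
  x <- seq(-nh, nh) * h
  y <- x
  n <- length(x)
  X <- matrix(x, n, n)
  Y <- matrix(y, n, n, byrow = TRUE)
  zb <- biconic_sag(X, Y, spec$r_flat, spec$r_steep, spec$axis_flat,
                    spec$q_flat, spec$q_steep)
  rho2 <- (X - spec$cone_center[1])^2 + (Y - spec$cone_center[2])^2
  bump <- exp(-rho2 / (2 * spec$cone_sigma^2))
  z_ant <- zb - spec$cone_amplitude * bump
  th_mm <- (spec$central_thickness - spec$cone_thinning * bump) / 1000
  z_post <- z_ant + th_mm
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
    z_ant <- z_ant + matrix(rnorm(n * n, 0, spec$noise_sd * 1e-3), n, n)
    z_post <- z_post + matrix(rnorm(n * n, 0, spec$noise_sd * 1e-3), n, n)
  }
  mask <- (X^2 + Y^2) <= (spec$grid_diameter / 2)^2 + 1e-9
  mask <- mask & is.finite(z_ant) & is.finite(z_post)
  # pachymetry: recomputed from the (noisy) surfaces when noise is present,
  # otherwise taken exactly from the generating thickness so that ties are
  # exact ties
  pachy <- if (spec$noise_sd > 0) (z_post - z_ant) * 1000 else
    spec$central_thickness - spec$cone_thinning * bump
  structure(list(x = x, y = y, z_ant = z_ant, z_post = z_post,
                 pachy = pachy, mask = mask,
                 spacing = h, diameter = spec$grid_diameter, spec = spec),
            class = "topography_grid")
}

#' @export
print.topography_grid <- function(x, ...) {
  cat(sprintf("topography_grid: %d x %d lattice, spacing %.3g mm, diameter %.3g mm\n",
              length(x$x), length(x$y), x$spacing, x$diameter))
  cat(sprintf("  valid points: %d; pachymetry %.0f-%.0f um\n",
              sum(x$mask), min(x$pachy[x$mask]), max(x$pachy[x$mask])))
  invisible(x)
}

#' Valid surface points of a topography grid
#'
#' @param grid a `topography_grid`
#' @param surface `"ant"` or `"post"`
#' @return n x 3 matrix of (x, y, z) in mm, one row per valid lattice node
#' @export
grid_points <- function(grid, surface = c("ant", "post")) {
  surface <- match.arg(surface)
  Z <- if (surface == "ant") grid$z_ant else grid$z_post
  idx <- which(grid$mask)
  n <- length(grid$x)
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  cbind(x = grid$x[i], y = grid$y[j], z = Z[idx])
}

#' Synthetic keratoconic cohort
#'
#' Draws `n` corneas around the study population's preoperative summary
#' statistics: steep/flat apical radii ~7.3/7.7 +- 0.5 mm, Kmax-t in the
#' 50-57 D range, minimum pachymetry ~463 +- 20 um, paracentral cone centres
#' 0.5-2 mm from the corneal apex (clinically typical decentration, inside
#' the 4 mm customized treatment zone).
#'
#' @param n number of corneas
#' @param seed integer seed; each cornea also receives its own derived seed
#' @param noise_sd elevation noise passed to each spec (um)
#' @return list of `topography_grid`
#' @export
synthetic_cohort <- function(n = 10, seed = 1L, noise_sd = 0) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    r_flat <- clamp(rnorm(1, 7.7, 0.35), 7.0, 8.6)
    r_steep <- clamp(r_flat - abs(rnorm(1, 0.35, 0.15)), 6.6, r_flat)
    sigma <- runif(1, 0.9, 1.4)
    kbase <- 0.5 * (KERATOMETRIC_INDEX_TANGENTIAL - 1) * 1000 *
      (1 / r_flat + 1 / r_steep)
    ktarget <- clamp(rnorm(1, 54, 2), 50, 57)
    amp <- max((ktarget - kbase) * sigma^2 / 337.5, 0.005)
    rc <- runif(1, 0.5, 2.0)   # paracentral cones, clinically typical decentration
    ac <- runif(1, 0, 2 * pi)
    ct <- clamp(rnorm(1, 540, 20), 480, 600)
    thin <- clamp(ct - rnorm(1, 463, 20), 30, 140)
    specs[[i]] <- cornea_spec(
      r_flat = r_flat, r_steep = r_steep, axis_flat = runif(1, 0, 180),
      q_flat = rnorm(1, -0.25, 0.08), q_steep = rnorm(1, -0.25, 0.08),
      cone_center = rc * c(cos(ac), sin(ac)), cone_amplitude = amp,
      cone_sigma = sigma, central_thickness = ct, cone_thinning = thin,
      noise_sd = noise_sd, seed = as.integer(seed) * 1000L + i)
  }
  lapply(specs, generate_cornea)
}

#' Average (keratoconus-free) cornea used for material calibration
#'
#' Biconic with the population mean radii and a 545 um uniform thickness;
#' no cone, no noise.
#'
#' @return a `cornea_spec`
#' @export
average_cornea_spec <- function() {
  cornea_spec(r_flat = 7.7, r_steep = 7.3, cone_amplitude = 0,
              cone_thinning = 0, central_thickness = 545)
}
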