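# Depth-varying anisotropic hyperelastic constitutive model: isochoric
# neo-Hookean matrix + two dispersed, tension-only collagen fiber families
# (Holzapfel-Gasser-Ogden generalized structure tensor form) + volumetric
# penalty. Effective parameters at each integration point combine the depth
# profile, the keratoconus weakening multiplier (applied to matrix and
# fibers) and the CXL stiffening multiplier (fibers only).

#' Constitutive parameters
#'
#' Shipped defaults: the exact calibrated constants of the source model are
#' not published, so `c` (matrix stiffness) and `k2` (fiber nonlinearity) are
#' set at literature scale for human stroma and `k1` is calibrated once so
#' that a uniform 16.3-fold fiber stiffening raises the apical-rise
#' tangential modulus of the average cornea at 15 mm Hg by about 105%
#' (the model's one printed anchor). See the methods vignette.
#'
#' @param c isotropic matrix stiffness (kPa)
#' @param k1 fiber family stiffness (kPa)
#' @param k2 fiber nonlinearity (dimensionless)
#' @param kappa fiber dispersion in `[0, 1/3]`
#' @param depth_ratio anterior/posterior stiffness ratio (1.68: anterior 68%
#'   stiffer)
#' @param bulk_penalty quasi-incompressibility penalty (kPa), `>= 1000 c`
#' @param kc_scope `"both"`: KC weakening multiplies matrix and fibers;
#'   `"fibers"`: fibers only
#' @return object of class `material_params`
#' @export
material_params <- function(c = 200, k1 = 90.5, k2 = 200, kappa = 0.2,
                            depth_ratio = 1.68, bulk_penalty = 1000 * c,
                            kc_scope = c("both", "fibers")) {
  kc_scope <- match.arg(kc_scope)
  stopifnot(c > 0, k1 >= 0, k2 > 0, kappa >= 0, kappa <= 1 / 3,
            depth_ratio > 0, bulk_penalty > 0)
  structure(list(c = c, k1 = k1, k2 = k2, kappa = kappa,
                 depth_ratio = depth_ratio, bulk_penalty = bulk_penalty,
                 kc_scope = kc_scope), class = "material_params")
}

#' Depth stiffness profile
#'
#' Linear in normalized depth with `s(0)/s(1) = depth_ratio` (anterior
#' stiffer) and unit mean over depth, so that the depth-averaged stiffness
#' equals the calibrated value.
#'
#' @param dhat normalized depth in `[0, 1]` (0 = anterior)
#' @param depth_ratio anterior/posterior ratio
#' @return scale factors
#' @export
depth_scale <- function(dhat, depth_ratio = 1.68) {
  if (any(dhat < -1e-9 | dhat > 1 + 1e-9)) {
    stop_cxl("normalized depth outside [0, 1]", "cxl_material_error")
  }
  dhat <- pmin(pmax(dhat, 0), 1)
  s1 <- 2 / (1 + depth_ratio)     # posterior value
  s0 <- depth_ratio * s1          # anterior value
  s0 + (s1 - s0) * dhat
}

#' Stress and consistent tangent of the fiber-reinforced law
#'
#' Evaluates the second Piola-Kirchhoff stress, first Piola-Kirchhoff stress,
#' Cauchy stress, strain energy and the consistent material tangent
#' (`dS/dE`, Voigt) at one material point. Fibers carry load only when their
#' dispersed strain measure is positive.
#'
#' @param F 3x3 deformation gradient (`det F > 0`)
#' @param params a `material_params` (or list with the same fields)
#' @param a1,a2 unit fiber direction vectors
#' @param multipliers optional list with `kc` and `cxl` multipliers applied
#'   at this point
#' @return list with `S`, `P`, `sigma`, `D` (6x6), `J`, `W`
#' @export
hgo_stress <- function(F, params, a1 = c(1, 0, 0), a2 = c(0, 1, 0),
                       multipliers = list()) {
  m_kc <- multipliers$kc %||% 1
  m_cxl <- multipliers$cxl %||% 1
  ceff <- params$c * (if ((params$kc_scope %||% "both") == "both") m_kc else 1)
  k1eff <- params$k1 * m_kc * m_cxl
  hgo_point(F, ceff, k1eff, params$k2, params$kappa, params$bulk_penalty,
            a1 / sqrt(sum(a1^2)), a2 / sqrt(sum(a2^2)))
}

# In-plane orthogonal fiber frame from surface normals: a1 ~ nasal-temporal
# (x) projected on the tangent plane, a2 = n x a1.
fiber_frame <- function(normals) {
  n <- normals / sqrt(rowSums(normals^2))
  ex <- matrix(rep(c(1, 0, 0), each = nrow(n)), ncol = 3)
  a1 <- ex - n * rowSums(ex * n)
  deg <- rowSums(a1^2) < 1e-8
  if (any(deg)) {
    ey <- matrix(rep(c(0, 1, 0), each = sum(deg)), ncol = 3)
    a1[deg, ] <- ey - n[deg, , drop = FALSE] * rowSums(ey * n[deg, , drop = FALSE])
  }
  a1 <- a1 / sqrt(rowSums(a1^2))
  a2 <- cbind(n[, 2] * a1[, 3] - n[, 3] * a1[, 2],
              n[, 3] * a1[, 1] - n[, 1] * a1[, 3],
              n[, 1] * a1[, 2] - n[, 2] * a1[, 1])
  list(a1 = a1, a2 = a2 / sqrt(rowSums(a2^2)))
}

#' Per-integration-point material field
#'
#' Combines the base parameters with the depth profile `s(dhat)`, the
#' keratoconus weakening multiplier `m_KC` (matrix and fibers, per
#' `kc_scope`) and the CXL stiffening multiplier `m_CXL` (fibers only):
#' effective `c = c s m_KC`, effective `k1 = k1 s m_KC m_CXL`. Fiber
#' directions are the in-plane orthogonal nasal-temporal / superior-inferior
#' families tangent to the anterior surface.
#'
#' @param mesh a `corneal_mesh`
#' @param params a [material_params()]
#' @param weakening optional `scalar_field` from [weakening_field()]
#' @param cxl optional `scalar_field` from [cxl_field()]
#' @return object of class `material_field`
#' @export
material_field <- function(mesh, params, weakening = NULL, cxl = NULL) {
  qp <- fem_qp_data(mesh$nodes, mesh$tets - 1L, mesh$dhat)
  pos <- qp$pos
  dhat <- pmin(pmax(as.numeric(qp$val), 0), 1)
  m <- nrow(mesh$tets)
  s <- depth_scale(dhat, params$depth_ratio)
  m_kc <- if (!is.null(weakening)) weakening$fun(pos[, 1], pos[, 2]) else rep(1, m * 4)
  if (!is.null(cxl)) {
    if (is.null(mesh$grid)) stop_cxl("CXL fields need a grid-backed mesh", "cxl_material_error")
    depth_um <- dhat * grid_interp(mesh$grid, pos[, 1], pos[, 2], "th") * 1000
    m_cxl <- cxl$fun(pos[, 1], pos[, 2], depth_um)
  } else m_cxl <- rep(1, m * 4)
  c_eff <- params$c * s * (if (params$kc_scope == "both") m_kc else 1)
  k1_eff <- params$k1 * s * m_kc * m_cxl
  if (!is.null(mesh$grid)) {
    g <- grid_gradient(mesh$grid, pos[, 1], pos[, 2], "ant")
    normals <- cbind(-g$zx, -g$zy, 1)
  } else {
    normals <- pos  # spherical shell: radial
  }
  fr <- fiber_frame(normals)
  as_m4 <- function(v) matrix(v, m, 4, byrow = TRUE)
  structure(list(
    c_eff = as_m4(c_eff), k1_eff = as_m4(k1_eff),
    k2 = as_m4(rep(params$k2, m * 4)), kappa = as_m4(rep(params$kappa, m * 4)),
    bulk = as_m4(rep(params$bulk_penalty, m * 4)),
    A1 = fr$a1, A2 = fr$a2, qp_pos = pos, qp_dhat = dhat,
    params = params, weakening = weakening, cxl = cxl),
    class = "material_field")
}
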