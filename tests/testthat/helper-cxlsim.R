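# Shared fixtures and independent oracles. Expensive FEM objects are
# computed lazily once per test session and reused across files (testthat
# loads helpers once per process; files run alphabetically, so
# test-acceptance.R usually pays for them first).

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# --- independent analytic sag / curvature oracle ----------------------------
# Re-implements the generating surface (biconic minus Gaussian cone) and
# differentiates it directly; never touches the package's surface code.
oracle_sag <- function(x, y, spec) {
  th <- spec$axis_flat * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  cx <- 1 / spec$r_flat
  cy <- 1 / spec$r_steep
  num <- cx * u^2 + cy * v^2
  rad <- 1 - (1 + spec$q_flat) * cx^2 * u^2 - (1 + spec$q_steep) * cy^2 * v^2
  z <- num / (1 + sqrt(rad))
  rho2 <- (x - spec$cone_center[1])^2 + (y - spec$cone_center[2])^2
  z - spec$cone_amplitude * exp(-rho2 / (2 * spec$cone_sigma^2))
}

# mean curvature of the sag surface in D (the sphere-fit tangential
# curvature converges to 337.5 * H as the neighborhood shrinks)
oracle_ktg <- function(x, y, spec, h = 1e-4) {
  f <- function(xx, yy) oracle_sag(xx, yy, spec)
  zx <- (f(x + h, y) - f(x - h, y)) / (2 * h)
  zy <- (f(x, y + h) - f(x, y - h)) / (2 * h)
  zxx <- (f(x + h, y) - 2 * f(x, y) + f(x - h, y)) / h^2
  zyy <- (f(x, y + h) - 2 * f(x, y) + f(x, y - h)) / h^2
  zxy <- (f(x + h, y + h) - f(x + h, y - h) - f(x - h, y + h) +
            f(x - h, y - h)) / (4 * h^2)
  H <- ((1 + zx^2) * zyy - 2 * zx * zy * zxy + (1 + zy^2) * zxx) /
    (2 * (1 + zx^2 + zy^2)^1.5)
  (1.3375 - 1) * 1000 * H
}

# --- shared geometries ------------------------------------------------------
kc_grid <- function() fixture("kc_grid", generate_cornea(cornea_spec()))

kc_map <- function() fixture("kc_map", tangential_curvature(kc_grid()))

kc_cone <- function() fixture("kc_cone", detect_cone(kc_map()))

# coarse desk-scale mesh used by all FEM tests
kc_mesh <- function() fixture("kc_mesh", {
  build_mesh(kc_grid(), layers = 3, edge_central = 0.65, edge_peripheral = 1.15)
})

test_solve_config <- function(iop = 15) solve_config(iop = iop, load_steps = 2)

# baseline inflation of the KC cornea (weakened, default material)
kc_weakening <- function() fixture("kc_weakening", {
  weakening_field(kc_cone(), 0.429, kc_mesh())
})

kc_material_fn <- function() {
  wf <- kc_weakening()
  function(m) material_field(m, material_params(), weakening = wf)
}

# stress-free recovery at 15 mm Hg, 1 um tolerance (acceptance criterion)
kc_prestress <- function() fixture("kc_prestress", {
  find_stress_free(kc_mesh(), kc_material_fn(), test_solve_config(),
                   tol = 1e-3, max_iter = 20)
})

# --- spherical shell fixture (solver oracle) --------------------------------
shell_constraints <- function(mesh) {
  nd <- mesh$nodes
  pick <- function(dir) which.max(nd %*% dir)
  A <- pick(c(1, 0, 0)); B <- pick(c(-1, 0, 0)); C <- pick(c(0, 1, 0))
  list(nodes = c(A, A, B, B, C, C),
       dirs = rbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 0), c(0, 0, 1),
                    c(1, 0, 0), c(0, 0, 1)))
}

shell_fixture <- function() fixture("shell", {
  mesh <- mesh_spherical_shell(radius = 7.7, thickness = 0.55, subdiv = 2,
                               layers = 2)
  cpar <- 100
  mat <- material_field(mesh, material_params(c = cpar, k1 = 0, k2 = 200,
                                              kappa = 0.2,
                                              bulk_penalty = 1000 * cpar))
  cons <- shell_constraints(mesh)
  sol <- inflate(mesh, mat, solve_config(iop = 2, load_steps = 1),
                 constraints = cons)
  list(mesh = mesh, mat = mat, cons = cons, sol = sol, cpar = cpar,
       p_kpa = 2 * 0.133322)
})

shell_radial_mid <- function(mesh, u) {
  U <- matrix(u, ncol = 3, byrow = TRUE)
  ur_of <- function(idx) {
    nd <- mesh$nodes[idx, , drop = FALSE]
    r0 <- sqrt(rowSums(nd^2))
    mean(rowSums((nd / r0) * U[idx, , drop = FALSE]))
  }
  (ur_of(mesh$anterior_nodes) + ur_of(mesh$posterior_nodes)) / 2
}

# --- cohort acceptance run (computed once, asserted in several tests) -------
cohort_protocols <- function() {
  list(cxl_protocol("standard"), cxl_protocol("custom_standard"),
       cxl_protocol("custom_elza"))
}

cohort_run <- function() fixture("cohort_run", {
  grids <- synthetic_cohort(3, seed = 1)
  reports <- list()
  for (g in grids) {
    reports <- c(reports,
                 simulate_protocols(g, cohort_protocols(),
                                    mesh_opts = list(layers = 3,
                                                     edge_central = 0.65,
                                                     edge_peripheral = 1.15),
                                    config = test_solve_config(),
                                    prestress_tol = 2e-3))
  }
  reports
})

delta_of <- function(reports, protocol, metric) {
  vapply(Filter(function(r) r$protocol == protocol, reports),
         function(r) unname(r$delta[metric]), 0)
}

# modulus anchor: default material on the average cornea (t6 analogue)
modulus_pair <- function() fixture("modulus_pair", {
  g <- generate_cornea(average_cornea_spec())
  mesh <- build_mesh(g, layers = 3, edge_central = 0.5, edge_peripheral = 0.9)
  cfg <- test_solve_config()
  pm <- material_params()
  e0 <- tangential_modulus_at_iop(mesh, material_field(mesh, pm), config = cfg)
  pm_cxl <- material_params(k1 = 16.3 * pm$k1)
  e1 <- tangential_modulus_at_iop(mesh, material_field(mesh, pm_cxl), config = cfg)
  list(e0 = e0, e1 = e1, mesh = mesh, cfg = cfg)
})
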