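# End-to-end CXL outcome prediction: metrics -> cone detection -> meshing ->
# weakening field -> pre-stress -> baseline inflation -> CXL field ->
# re-inflation from the same stress-free state -> resampled metrics ->
# deltas (post - pre). Pre and post metrics are both computed on FEM
# surfaces resampled to the input lattice so they share support exactly
# (a null treatment then gives deltas that are identically zero).

METRIC_NAMES <- c("kmax_t", "kmaxmean3", "pachy_min", "R_steep", "R_flat",
                  "axis", "sphere", "cylinder", "spherical_equivalent")

# curvature_radius: sphere-fit neighborhood; FEM-resampled surfaces use a
# wider one (0.25 mm) to suppress element-scale resampling wiggle, which
# corrupts max statistics. Kmax is taken in the central 8 mm (the clinically
# reliable zone; also avoids rim artifacts of the meshed domain).
metrics_bundle <- function(grid, curvature_radius = 0.12, kmax_diameter = 8) {
  map <- tangential_curvature(grid, neighborhood_radius = curvature_radius)
  central <- map$x^2 + map$y^2 <= (kmax_diameter / 2)^2
  km <- kmax_metrics(map[central, , drop = FALSE])
  bf <- fit_biconic(grid)
  mp <- min_pachymetry(grid)
  list(metrics = c(kmax_t = km$kmax_t, kmaxmean3 = km$kmaxmean3,
                   pachy_min = unname(mp$value), R_steep = bf$R_steep,
                   R_flat = bf$R_flat, axis = bf$axis, sphere = bf$sphere,
                   cylinder = bf$cylinder,
                   spherical_equivalent = bf$spherical_equivalent),
       kmax_location = km$location, map = map, biconic = bf)
}

# Resample deformed FEM surfaces back onto the input lattice.
fem_to_grid <- function(mesh, deformed, grid) {
  rmax <- mesh$config$diameter / 2 - 0.15
  n <- length(grid$x)
  X <- matrix(grid$x, n, n)
  Y <- matrix(grid$y, n, n, byrow = TRUE)
  sel <- which(X^2 + Y^2 <= rmax^2)
  qx <- X[sel]; qy <- Y[sel]
  za <- resample_quadratic(deformed[mesh$anterior_nodes, , drop = FALSE], qx, qy, 12L)
  zp <- resample_quadratic(deformed[mesh$posterior_nodes, , drop = FALSE], qx, qy, 12L)
  z_ant <- matrix(NA_real_, n, n); z_post <- matrix(NA_real_, n, n)
  z_ant[sel] <- za; z_post[sel] <- zp
  mask <- is.finite(z_ant) & is.finite(z_post)
  structure(list(x = grid$x, y = grid$y, z_ant = z_ant, z_post = z_post,
                 pachy = (z_post - z_ant) * 1000, mask = mask,
                 spacing = grid$spacing, diameter = 2 * rmax, spec = NULL),
            class = "topography_grid")
}

# Mean tangential-curvature change inside/outside the cone within the 6 mm
# optical zone; maps must share the input lattice.
zone_curvature_delta <- function(map_pre, map_post, cone, zone_diameter = 6) {
  stopifnot(nrow(map_pre) == nrow(map_post))
  lattice <- attr(map_pre, "lattice")
  member <- lattice$idx %in% cone$lattice_members
  ok <- map_pre$valid & map_post$valid &
    (map_pre$x^2 + map_pre$y^2 <= (zone_diameter / 2)^2)
  dk <- map_post$K_tg - map_pre$K_tg
  list(cone = mean(dk[ok & member]), noncone = mean(dk[ok & !member]))
}

#' Simulate one or several CXL protocols on a cornea
#'
#' `simulate_protocols()` runs the full pipeline once per cornea and reuses
#' the mesh, weakening field and stress-free geometry across protocols
#' (protocol choice only alters the CXL multiplier field).
#' `simulate_protocol()` is the single-protocol convenience wrapper.
#'
#' @param grid a `topography_grid`
#' @param protocols list of [cxl_protocol()] objects
#' @param protocol a single [cxl_protocol()]
#' @param iop intraocular pressure (mm Hg)
#' @param alpha_kc retained stiffness at the cone centre (0.429 gives the
#'   57% reduction used by default)
#' @param material a [material_params()]
#' @param mesh_opts list of [build_mesh()] arguments (desk-scale default:
#'   `layers = 3`; the reference configuration uses `layers = 7` with
#'   0.18/0.35 mm edges)
#' @param config a [solve_config()]
#' @param prestress_tol,prestress_max_iter,prestress_relax passed to
#'   [find_stress_free()]
#' @param fem_curvature_radius sphere-fit neighborhood radius (mm) for
#'   metrics on FEM-resampled surfaces
#' @param prestress_init optional stress-free coordinate warm start (node
#'   matrix from a nearby configuration's `stress_free_nodes`)
#' @return `simulate_protocols()`: list of `outcome_report`;
#'   `simulate_protocol()`: a single `outcome_report` with `pre`, `post` and
#'   `delta` (post - pre) metric vectors plus the mean tangential-curvature
#'   change inside (`dK_cone`) and outside (`dK_noncone`) the cone in the
#'   6 mm zone
#' @export
simulate_protocols <- function(grid, protocols, iop = 15, alpha_kc = 0.429,
                               material = material_params(),
                               mesh_opts = list(layers = 3,
                                                edge_central = 0.4,
                                                edge_peripheral = 0.7),
                               config = solve_config(iop = iop),
                               prestress_tol = 1e-3,
                               prestress_max_iter = 20,
                               prestress_relax = 1,
                               fem_curvature_radius = 0.25,
                               prestress_init = NULL) {
  stopifnot(inherits(grid, "topography_grid"))
  config$iop <- iop
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_cxl(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "cxl_pipeline_error")
    })
  }
  input <- stage("metrics(pre)", metrics_bundle(grid))
  cone <- tryCatch(detect_cone(input$map), cxl_empty_cone = function(e) NULL)
  need_cone <- any(vapply(protocols, function(p) p$centered_on_cone, TRUE)) ||
    alpha_kc < 1
  if (is.null(cone) && need_cone) {
    stop_cxl("no keratoconus cone detected but a cone-centred protocol or weakening was requested",
             "cxl_pipeline_error")
  }
  mesh <- stage("mesh", do.call(build_mesh, c(list(grid), mesh_opts)))
  wf <- if (alpha_kc < 1) {
    stage("weakening_field", weakening_field(cone, alpha_kc, mesh))
  } else NULL
  material_fn <- function(m) material_field(m, material, weakening = wf)
  ps <- stage("pre-stress",
              find_stress_free(mesh, material_fn, config, tol = prestress_tol,
                               max_iter = prestress_max_iter,
                               relax = prestress_relax,
                               X_init = prestress_init))
  sol_pre <- ps$solution
  grid_pre <- stage("resample(pre)", fem_to_grid(mesh, sol_pre$deformed, grid))
  pre <- stage("metrics(FEM pre)",
               metrics_bundle(grid_pre, curvature_radius = fem_curvature_radius))
  mat0 <- material_fn(ps$mesh0)
  lapply(protocols, function(protocol) {
    cf <- stage(paste0("cxl_field(", protocol$name, ")"),
                cxl_field(protocol, ps$mesh0, cone))
    mat_post <- material_field(ps$mesh0, material, weakening = wf, cxl = cf)
    sol_post <- stage(paste0("inflate(post ", protocol$name, ")"),
                      inflate(ps$mesh0, mat_post, config, u0 = sol_pre$u))
    grid_post <- fem_to_grid(ps$mesh0, sol_post$deformed, grid)
    post <- stage(paste0("metrics(post ", protocol$name, ")"),
                  metrics_bundle(grid_post,
                                 curvature_radius = fem_curvature_radius))
    zd <- if (!is.null(cone)) {
      zone_curvature_delta(pre$map, post$map, cone)
    } else list(cone = NA_real_, noncone = NA_real_)
    structure(list(
      protocol = protocol$name, iop = iop, alpha_kc = alpha_kc,
      input = input$metrics, pre = pre$metrics, post = post$metrics,
      delta = post$metrics - pre$metrics,
      dK_cone = zd$cone, dK_noncone = zd$noncone,
      cone_center = if (!is.null(cone)) cone$center else NULL,
      cone_fraction = if (!is.null(cone)) cone$fraction else NA_real_,
      prestress_residual = ps$residual,
      prestress_iterations = ps$iterations,
      stress_free_nodes = ps$mesh0$nodes,
      max_volume_change = max(sol_pre$max_volume_change,
                              sol_post$max_volume_change)),
      class = "outcome_report")
  })
}

#' @rdname simulate_protocols
#' @export
simulate_protocol <- function(grid, protocol, iop = 15, alpha_kc = 0.429, ...) {
  simulate_protocols(grid, list(protocol), iop = iop, alpha_kc = alpha_kc,
                     ...)[[1]]
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("outcome_report: protocol %s, IOP %g mm Hg, alpha_KC %.3f\n",
              x$protocol, x$iop, x$alpha_kc))
  df <- data.frame(pre = x$pre, post = x$post, delta = x$delta)
  print(round(df, 3))
  cat(sprintf("  mean dK_tg (6 mm zone): cone %.3f D, non-cone %.3f D\n",
              x$dK_cone, x$dK_noncone))
  invisible(x)
}

#' Cohort summary with ANOVA and Tukey post-hoc tests
#'
#' Tabulates per-protocol means and SDs of the outcome deltas and compares
#' protocols by one-way ANOVA with Tukey's HSD (standard library routines).
#'
#' @param reports flat list of `outcome_report` (several corneas x several
#'   protocols); at least 2 protocols with >= 3 corneas each
#' @param metrics metric names to tabulate
#' @return object of class `cohort_report`: `table` (mean/SD per protocol per
#'   metric), `anova_p`, `tukey` (pairwise p-value matrices per metric)
#' @export
cohort_report <- function(reports, metrics = c("kmaxmean3", "kmax_t",
                                               "pachy_min", "R_steep",
                                               "R_flat", "sphere", "cylinder",
                                               "spherical_equivalent")) {
  proto <- vapply(reports, function(r) r$protocol, "")
  if (length(unique(proto)) < 2 || min(table(proto)) < 3) {
    stop_cxl("cohort_report needs >= 2 protocols with >= 3 corneas each",
             "cxl_pipeline_error")
  }
  rows <- list(); anova_p <- c(); tukey <- list()
  for (mname in metrics) {
    v <- vapply(reports, function(r) unname(r$delta[mname]), 0)
    df <- data.frame(delta = v, protocol = factor(proto))
    agg <- tapply(df$delta, df$protocol, function(z) c(mean = mean(z), sd = sd(z)))
    for (p in names(agg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mname, protocol = p, mean = agg[[p]]["mean"],
        sd = agg[[p]]["sd"], n = sum(proto == p))
    }
    fit <- aov(delta ~ protocol, data = df)
    anova_p[mname] <- summary(fit)[[1]][["Pr(>F)"]][1]
    tukey[[mname]] <- TukeyHSD(fit)$protocol
  }
  structure(list(table = do.call(rbind, rows), anova_p = anova_p,
                 tukey = tukey), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report (delta = post - pre):\n")
  print(transform(x$table, mean = round(mean, 3), sd = round(sd, 3)),
        row.names = FALSE)
  cat("ANOVA p-values:\n")
  print(signif(x$anova_p, 3))
  invisible(x)
}

#' IOP / alpha_KC sensitivity grid
#'
#' Re-runs one protocol over a grid of intraocular pressures and keratoconus
#' weakening levels and reports the cohort-mean `delta KmaxMean3` per cell
#' plus its percentage variation relative to the reference cell
#' (IOP 15 mm Hg, alpha_KC 0.429). In `"cross"` mode one parameter varies
#' while the other stays at its reference; `"full"` evaluates the whole grid.
#' Failed cells are marked invalid and the run continues.
#'
#' @param grids list of `topography_grid` (the sensitivity cohort)
#' @param protocol a [cxl_protocol()]
#' @param iops IOP values (mm Hg)
#' @param alphas alpha_KC values
#' @param mode `"cross"` or `"full"`
#' @param ref reference cell `c(iop, alpha)`
#' @param ... forwarded to [simulate_protocol()]
#' @return object of class `sensitivity_table`: data frame with `iop`,
#'   `alpha`, `mean_dkmaxmean3`, `sd`, `n_ok`, `pct_variation`; per-cornea
#'   values in `attr(, "values")`
#' @export
sensitivity_grid <- function(grids, protocol, iops = c(13, 15, 18, 20),
                             alphas = c(0.3, 0.429, 0.55, 0.7),
                             mode = c("cross", "full"),
                             ref = c(15, 0.429), ...) {
  mode <- match.arg(mode)
  cells <- if (mode == "full") {
    expand.grid(iop = iops, alpha = alphas)
  } else {
    unique(rbind(data.frame(iop = iops, alpha = ref[2]),
                 data.frame(iop = ref[1], alpha = alphas)))
  }
  if (!any(abs(cells$iop - ref[1]) < 1e-9 & abs(cells$alpha - ref[2]) < 1e-9)) {
    cells <- rbind(cells, data.frame(iop = ref[1], alpha = ref[2]))
  }
  iref <- which(abs(cells$iop - ref[1]) < 1e-9 & abs(cells$alpha - ref[2]) < 1e-9)[1]
  vals <- matrix(NA_real_, nrow(cells), length(grids))
  # reference cell first; its stress-free geometry warm-starts the others
  order_cells <- c(iref, setdiff(seq_len(nrow(cells)), iref))
  for (gi in seq_along(grids)) {
    x0 <- NULL
    for (ci in order_cells) {
      rep_ci <- tryCatch(
        simulate_protocol(grids[[gi]], protocol, iop = cells$iop[ci],
                          alpha_kc = cells$alpha[ci], prestress_init = x0, ...),
        error = function(e) NULL)
      if (!is.null(rep_ci)) {
        vals[ci, gi] <- rep_ci$delta[["kmaxmean3"]]
        if (ci == iref) x0 <- rep_ci$stress_free_nodes
      }
    }
  }
  mean_d <- rowMeans(vals, na.rm = TRUE)
  out <- data.frame(cells,
                    mean_dkmaxmean3 = mean_d,
                    sd = apply(vals, 1, sd, na.rm = TRUE),
                    n_ok = rowSums(is.finite(vals)),
                    pct_variation = 100 * (mean_d - mean_d[iref]) / abs(mean_d[iref]))
  attr(out, "values") <- vals
  attr(out, "ref") <- ref
  class(out) <- c("sensitivity_table", "data.frame")
  out
}
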