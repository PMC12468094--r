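# Quadratic tetrahedral meshing: a graded triangulated disc is extruded
# through the corneal thickness into prisms, each split into three
# tetrahedra with index-based diagonals (conforming across neighbors), then
# promoted to 10-node tetrahedra with mid-edge nodes re-projected onto the
# interpolated surfaces.

# Graded concentric-ring triangulation of a disc of radius R.
# Edge target: edge_central inside `central_radius`, ramping linearly to
# edge_peripheral at the rim. Rings with different node counts are stitched
# by an angular two-pointer walk; all triangles CCW (+z normal).
disc_triangulation <- function(R, edge_central, edge_peripheral,
                               central_radius = 3) {
  hfun <- function(r) {
    if (R <= central_radius) return(rep(edge_central, length(r)))
    ifelse(r <= central_radius, edge_central,
           edge_central + (edge_peripheral - edge_central) *
             (r - central_radius) / (R - central_radius))
  }
  radii <- numeric(0)
  r <- 0
  repeat {
    dr <- hfun(r)[1]
    r <- r + dr
    if (r >= R - 0.35 * dr) { radii <- c(radii, R); break }
    radii <- c(radii, r)
  }
  nring <- length(radii)
  counts <- integer(nring)
  xy <- matrix(0, 1, 2)
  ring <- 0L
  for (k in seq_len(nring)) {
    nk <- max(6L, as.integer(round(2 * pi * radii[k] / hfun(radii[k])[1])))
    if (k > 1) nk <- min(max(nk, counts[k - 1]), 2L * counts[k - 1])
    counts[k] <- nk
    ang <- 2 * pi * (seq_len(nk) - 1) / nk
    xy <- rbind(xy, cbind(radii[k] * cos(ang), radii[k] * sin(ang)))
    ring <- c(ring, rep.int(k, nk))
  }
  starts <- cumsum(c(2L, counts))[seq_len(nring)]
  tris <- matrix(0L, 0, 3)
  # centre fan
  ids1 <- starts[1] + seq_len(counts[1]) - 1L
  fan <- cbind(1L, ids1, c(ids1[-1], ids1[1]))
  tris <- rbind(tris, fan)
  stitch <- function(idsA, idsB) {
    nA <- length(idsA); nB <- length(idsB)
    out <- matrix(0L, nA + nB, 3)
    i <- 0L; j <- 0L; t <- 0L
    while (i < nA || j < nB) {
      advA <- (i < nA) && (j >= nB || (i + 1) / nA <= (j + 1) / nB)
      t <- t + 1L
      if (advA) {
        out[t, ] <- c(idsA[(i + 1L) %% nA + 1L], idsA[i %% nA + 1L],
                      idsB[j %% nB + 1L])
        i <- i + 1L
      } else {
        out[t, ] <- c(idsB[j %% nB + 1L], idsB[(j + 1L) %% nB + 1L],
                      idsA[i %% nA + 1L])
        j <- j + 1L
      }
    }
    out[seq_len(t), , drop = FALSE]
  }
  if (nring > 1) {
    for (k in seq_len(nring - 1)) {
      idsA <- starts[k] + seq_len(counts[k]) - 1L
      idsB <- starts[k + 1] + seq_len(counts[k + 1]) - 1L
      tris <- rbind(tris, stitch(idsA, idsB))
    }
  }
  list(xy = xy, ring = ring, tris = tris, nring = nring)
}

# Split extruded prisms into 3 tets each. Lateral triangle indices are sorted
# (a < b < c) so that every vertical quad's diagonal runs from the smaller
# lateral index at the lower level -- consistent across neighbors.
extrude_prisms <- function(tris, nlat, layers) {
  S <- t(apply(tris, 1, sort))
  tet4 <- vector("list", layers)
  for (k in seq_len(layers) - 1L) {
    a0 <- k * nlat + S[, 1]; b0 <- k * nlat + S[, 2]; c0 <- k * nlat + S[, 3]
    a1 <- a0 + nlat; b1 <- b0 + nlat; c1 <- c0 + nlat
    tet4[[k + 1]] <- rbind(cbind(a0, b0, c0, c1),
                           cbind(a0, b0, c1, b1),
                           cbind(a0, b1, c1, a1))
  }
  do.call(rbind, tet4)
}

# Fix tet orientation (positive signed volume) by swapping nodes 2 and 3.
orient_tets <- function(tet4, coords) {
  v0 <- coords[tet4[, 1], , drop = FALSE]
  d1 <- coords[tet4[, 2], , drop = FALSE] - v0
  d2 <- coords[tet4[, 3], , drop = FALSE] - v0
  d3 <- coords[tet4[, 4], , drop = FALSE] - v0
  vol6 <- d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
    d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
    d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])
  neg <- vol6 < 0
  if (any(neg)) {
    tmp <- tet4[neg, 2]
    tet4[neg, 2] <- tet4[neg, 3]
    tet4[neg, 3] <- tmp
  }
  tet4
}

# Promote 4-node tets to 10-node (VTK edge order 01,12,02,03,13,23).
# Returns the tet10 connectivity, the unique edge parent pairs, and a lookup
# function for the mid node of a corner pair.
promote_tet10 <- function(tet4, ncorner) {
  ep <- rbind(tet4[, c(1, 2)], tet4[, c(2, 3)], tet4[, c(1, 3)],
              tet4[, c(1, 4)], tet4[, c(2, 4)], tet4[, c(3, 4)])
  lo <- pmin(ep[, 1], ep[, 2])
  hi <- pmax(ep[, 1], ep[, 2])
  key <- (lo - 1) * ncorner + (hi - 1)      # exact doubles
  ukey <- sort(unique(key))
  mid <- match(key, ukey) + ncorner
  m <- nrow(tet4)
  tet10 <- cbind(tet4,
                 mid[1:m], mid[(m + 1):(2 * m)], mid[(2 * m + 1):(3 * m)],
                 mid[(3 * m + 1):(4 * m)], mid[(4 * m + 1):(5 * m)],
                 mid[(5 * m + 1):(6 * m)])
  p1 <- floor(ukey / ncorner) + 1
  p2 <- ukey - (p1 - 1) * ncorner + 1
  midlookup <- function(a, b) {
    k <- (pmin(a, b) - 1) * ncorner + (pmax(a, b) - 1)
    match(k, ukey) + ncorner
  }
  list(tet10 = tet10, parents = cbind(p1, p2), midlookup = midlookup)
}

#' Build a labeled quadratic tetrahedral corneal mesh
#'
#' Extrudes a graded triangulated disc (finer in the central 6 mm) through
#' the corneal thickness into `layers` element layers of 10-node tetrahedra.
#' Nodes carry normalized depth (0 anterior, 1 posterior); the limbus is the
#' outermost lateral node ring at all depths. Deterministic for fixed inputs.
#'
#' @param grid a `topography_grid`
#' @param layers number of element layers through the thickness (>= 2);
#'   the reference configuration uses 7
#' @param edge_central target lateral edge length in the central 6 mm (mm)
#' @param edge_peripheral target lateral edge length at the rim (mm)
#' @param diameter meshed diameter (mm); defaults to slightly inside the grid
#' @return object of class `corneal_mesh`
#' @export
build_mesh <- function(grid, layers = 7, edge_central = 0.25,
                       edge_peripheral = 0.5, diameter = NULL) {
  stopifnot(inherits(grid, "topography_grid"), layers >= 2)
  if (any(grid$pachy[grid$mask] <= 0)) {
    stop_cxl("grid has non-positive thickness: surfaces cross (pathological input)",
             "cxl_mesh_error")
  }
  diameter <- diameter %||% min(9.5, grid$diameter - 6 * grid$spacing)
  disc <- disc_triangulation(diameter / 2, edge_central, edge_peripheral)
  nlat <- nrow(disc$xy)
  ncorner <- nlat * (layers + 1)
  lat_of <- rep(seq_len(nlat), layers + 1)
  level_of <- rep(0:layers, each = nlat)
  xc <- disc$xy[lat_of, 1]
  yc <- disc$xy[lat_of, 2]
  dc <- level_of / layers
  tet4 <- extrude_prisms(disc$tris, nlat, layers)
  # straight-corner coordinates for orientation
  thc <- grid_interp(grid, xc, yc, "th")
  zac <- grid_interp(grid, xc, yc, "ant")
  coords_c <- cbind(xc, yc, zac + dc * thc)
  tet4 <- orient_tets(tet4, coords_c)
  pro <- promote_tet10(tet4, ncorner)
  p1 <- pro$parents[, 1]; p2 <- pro$parents[, 2]
  xm <- (xc[p1] + xc[p2]) / 2
  ym <- (yc[p1] + yc[p2]) / 2
  dm <- (dc[p1] + dc[p2]) / 2
  # project rim mid-edge nodes onto the circular boundary so the quadratic
  # elements follow the meshed circle instead of its inscribed polygon
  rim_lat <- disc$ring == disc$nring
  on_rim <- rim_lat[lat_of[p1]] & rim_lat[lat_of[p2]]
  if (any(on_rim)) {
    rm0 <- sqrt(xm[on_rim]^2 + ym[on_rim]^2)
    scale <- (diameter / 2) / rm0
    xm[on_rim] <- xm[on_rim] * scale
    ym[on_rim] <- ym[on_rim] * scale
  }
  thm <- grid_interp(grid, xm, ym, "th")
  zam <- grid_interp(grid, xm, ym, "ant")
  nodes <- rbind(coords_c, cbind(xm, ym, zam + dm * thm))
  dhat <- c(dc, dm)
  rlat <- sqrt(c(xc, xm)^2 + c(yc, ym)^2)
  # labels
  anterior <- which(dhat == 0)
  posterior <- which(dhat == 1)
  rim_lat <- which(disc$ring == disc$nring)
  is_rim_corner <- lat_of %in% rim_lat
  rim_mid <- is_rim_corner[p1] & is_rim_corner[p2]
  limbus <- c(which(is_rim_corner), which(rim_mid) + ncorner)
  # surface faces with mid nodes
  mk_faces <- function(tris, level, flip) {
    off <- level * nlat
    a <- tris[, 1] + off; b <- tris[, 2] + off; c3 <- tris[, 3] + off
    if (flip) { tmp <- b; b <- c3; c3 <- tmp }
    cbind(a, b, c3, pro$midlookup(a, b), pro$midlookup(b, c3),
          pro$midlookup(a, c3))
  }
  post_faces <- mk_faces(disc$tris, layers, flip = FALSE)  # outward ~ +z
  ant_faces <- mk_faces(disc$tris, 0L, flip = TRUE)        # outward ~ -z
  # Sliding BC: the anchoring cone is swept by the ring's outward surface
  # normals, so its tangent plane is spanned by the normal and the
  # circumferential direction; the constrained direction is the meridional
  # in-plane direction m (radial projected onto the corneal tangent plane).
  lx <- nodes[limbus, 1]; ly <- nodes[limbus, 2]
  ga <- grid_gradient(grid, lx, ly, "ant")
  gt <- grid_gradient(grid, lx, ly, "th")
  zx <- ga$zx + 0.5 * gt$zx
  zy <- ga$zy + 0.5 * gt$zy
  nn <- cbind(-zx, -zy, 1) / sqrt(zx^2 + zy^2 + 1)
  rr <- sqrt(lx^2 + ly^2)
  er <- cbind(lx / rr, ly / rr, 0)
  mm <- er - nn * rowSums(er * nn)
  mm <- mm / sqrt(rowSums(mm^2))
  mesh <- structure(list(
    nodes = nodes, tets = pro$tet10, dhat = dhat, rlat = rlat,
    anterior_nodes = anterior, posterior_nodes = posterior,
    limbus_nodes = limbus, bc_normal = mm,
    pressure_faces = post_faces, anterior_faces = ant_faces,
    columns = list(nlat = nlat, layers = layers, lat_of = lat_of,
                   level_of = level_of, ncorner = ncorner),
    grid = grid,
    config = list(layers = layers, edge_central = edge_central,
                  edge_peripheral = edge_peripheral, diameter = diameter)),
    class = "corneal_mesh")
  vs <- fem_volumes(mesh$nodes, mesh$tets - 1L, numeric(3 * nrow(nodes)))
  if (vs$minJ0 <= 0) {
    bad <- which(vs$vol0 <= 0)
    stop_cxl(sprintf("meshing produced inverted elements (e.g. ids %s)",
                     paste(head(bad, 5), collapse = ", ")), "cxl_mesh_error")
  }
  mesh$volume <- sum(vs$vol0)
  mesh
}

#' @export
print.corneal_mesh <- function(x, ...) {
  cat(sprintf("corneal_mesh: %d nodes, %d quadratic tets, %d layers, diameter %.2f mm, volume %.2f mm^3\n",
              nrow(x$nodes), nrow(x$tets), x$config$layers,
              x$config$diameter, x$volume))
  invisible(x)
}

# --- closed spherical shell (solver verification) ---------------------------

icosphere <- function(subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    ep <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    key <- (pmin(ep[, 1], ep[, 2]) - 1) * nv + pmax(ep[, 1], ep[, 2]) - 1
    ukey <- sort(unique(key))
    mid <- match(key, ukey) + nv
    pa <- floor(ukey / nv) + 1
    pb <- ukey - (pa - 1) * nv + 1
    vm <- v[pa, ] + v[pb, ]
    vm <- vm / sqrt(rowSums(vm^2))
    v <- rbind(v, vm)
    m <- nrow(f)
    m01 <- mid[1:m]; m12 <- mid[(m + 1):(2 * m)]; m02 <- mid[(2 * m + 1):(3 * m)]
    f <- rbind(cbind(f[, 1], m01, m02), cbind(m01, f[, 2], m12),
               cbind(m02, m12, f[, 3]), cbind(m01, m12, m02))
  }
  # enforce outward CCW
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  flip <- rowSums(ctr * nrm) < 0
  if (any(flip)) { tmp <- f[flip, 2]; f[flip, 2] <- f[flip, 3]; f[flip, 3] <- tmp }
  list(v = v, f = f)
}

#' Closed thin spherical shell mesh (verification geometry)
#'
#' Quadratic tetrahedral mesh of a closed spherical shell of mid-surface
#' radius `radius` and thickness `thickness`, with pressure faces on the
#' inner surface. Used to verify the inflation solver against the linear
#' thin-shell closed form.
#'
#' @param radius mid-surface radius (mm)
#' @param thickness shell thickness (mm)
#' @param subdiv icosphere subdivisions (3 gives 1280 surface triangles)
#' @param layers element layers through the thickness
#' @return object of class `corneal_mesh` (labels: anterior = outer surface)
#' @export
mesh_spherical_shell <- function(radius = 7.7, thickness = 0.55, subdiv = 3,
                                 layers = 2) {
  ico <- icosphere(subdiv)
  nlat <- nrow(ico$v)
  ncorner <- nlat * (layers + 1)
  lat_of <- rep(seq_len(nlat), layers + 1)
  level_of <- rep(0:layers, each = nlat)
  rin <- radius - thickness / 2
  rad_c <- rin + level_of / layers * thickness
  coords_c <- ico$v[lat_of, ] * rad_c
  tet4 <- extrude_prisms(ico$f, nlat, layers)
  tet4 <- orient_tets(tet4, coords_c)
  pro <- promote_tet10(tet4, ncorner)
  p1 <- pro$parents[, 1]; p2 <- pro$parents[, 2]
  dirm <- ico$v[lat_of[p1], ] + ico$v[lat_of[p2], ]
  dirm <- dirm / sqrt(rowSums(dirm^2))
  radm <- (rad_c[p1] + rad_c[p2]) / 2
  nodes <- rbind(coords_c, dirm * radm)
  dhat <- c(level_of, (level_of[p1] + level_of[p2]) / 2) / layers
  # inner faces, oriented so cross(g_xi, g_eta) points to the cavity (-radial)
  inner <- cbind(ico$f[, 1], ico$f[, 3], ico$f[, 2])
  faces <- cbind(inner, pro$midlookup(inner[, 1], inner[, 2]),
                 pro$midlookup(inner[, 2], inner[, 3]),
                 pro$midlookup(inner[, 1], inner[, 3]))
  mesh <- structure(list(
    nodes = nodes, tets = pro$tet10, dhat = dhat,
    rlat = sqrt(nodes[, 1]^2 + nodes[, 2]^2),
    anterior_nodes = which(dhat == 1), posterior_nodes = which(dhat == 0),
    limbus_nodes = integer(0), bc_normal = NULL,
    pressure_faces = faces, anterior_faces = NULL,
    columns = list(nlat = nlat, layers = layers, lat_of = lat_of,
                   level_of = level_of, ncorner = ncorner),
    grid = NULL,
    config = list(layers = layers, radius = radius, thickness = thickness,
                  shell = TRUE)),
    class = "corneal_mesh")
  vs <- fem_volumes(mesh$nodes, mesh$tets - 1L, numeric(3 * nrow(nodes)))
  if (vs$minJ0 <= 0) stop_cxl("shell mesh has inverted elements", "cxl_mesh_error")
  mesh$volume <- sum(vs$vol0)
  mesh
}
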