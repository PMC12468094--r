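# Quadratic tetrahedral meshing of the corneal shell.

test_that("default configuration spans the thickness with 7 element layers", {
  mesh <- fixture("mesh7", build_mesh(kc_grid()))
  expect_equal(mesh$config$layers, 7)
  expect_equal(sort(unique(mesh$dhat[seq_len(mesh$columns$ncorner)])),
               (0:7) / 7)
  # one column of corner nodes per lateral node, monotone depth
  expect_equal(mesh$columns$layers, 7)
})

test_that("test mesh is valid: positive Jacobians, disjoint covering labels", {
  mesh <- kc_mesh()
  vols <- cxlsim:::fem_volumes(mesh$nodes, mesh$tets - 1L,
                               numeric(3 * nrow(mesh$nodes)))
  expect_gt(vols$minJ0, 0)
  expect_true(all(mesh$dhat[mesh$anterior_nodes] == 0))
  expect_true(all(mesh$dhat[mesh$posterior_nodes] == 1))
  expect_length(intersect(mesh$anterior_nodes, mesh$posterior_nodes), 0)
  # limbus nodes sit on the meshed rim at all depths (mid-edge nodes of the
  # ring lie on chords, slightly inside the circumradius)
  rl <- mesh$rlat[mesh$limbus_nodes]
  expect_true(all(rl <= mesh$config$diameter / 2 + 1e-9))
  expect_true(all(rl >= 0.98 * mesh$config$diameter / 2))
  expect_gt(length(unique(mesh$dhat[mesh$limbus_nodes])), 3)
})

test_that("meshing is deterministic", {
  m1 <- build_mesh(kc_grid(), layers = 3, edge_central = 0.6,
                   edge_peripheral = 1.0)
  m2 <- build_mesh(kc_grid(), layers = 3, edge_central = 0.6,
                   edge_peripheral = 1.0)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
})

test_that("mesh volume matches the analytic shell volume within 0.5%", {
  mesh <- kc_mesh()
  spec <- cornea_spec()
  # analytic thickness integral over the meshed disc (polar quadrature:
  # exact circular boundary)
  R <- mesh$config$diameter / 2
  nr <- 400; nt <- 720
  rr <- (seq_len(nr) - 0.5) * R / nr
  tt <- (seq_len(nt) - 0.5) * 2 * pi / nt
  gq <- expand.grid(r = rr, t = tt)
  px <- gq$r * cos(gq$t); py <- gq$r * sin(gq$t)
  rho2 <- (px - spec$cone_center[1])^2 + (py - spec$cone_center[2])^2
  th_mm <- (spec$central_thickness -
              spec$cone_thinning * exp(-rho2 / (2 * spec$cone_sigma^2))) / 1000
  vol_ref <- sum(th_mm * gq$r) * (R / nr) * (2 * pi / nt)
  expect_lt(abs(mesh$volume - vol_ref) / vol_ref, 0.005)
})

test_that("normalized depth is monotone along every through-thickness column", {
  mesh <- kc_mesh()
  cols <- mesh$columns
  for (l in c(1L, 7L, cols$nlat %/% 2L)) {
    ids <- l + cols$nlat * (0:cols$layers)
    expect_true(all(diff(mesh$dhat[ids]) > 0))
    # columns are vertical: shared lateral coordinates
    expect_lt(max(abs(diff(mesh$nodes[ids, 1]))), 1e-12)
  }
})

test_that("pathological grids raise a meshing error", {
  g <- kc_grid()
  # fold the anterior surface through the posterior one
  g$z_ant <- g$z_post + 0.2
  g$pachy <- (g$z_post - g$z_ant) * 1000
  expect_error(build_mesh(g, layers = 3, edge_central = 0.6,
                          edge_peripheral = 1.0),
               class = "cxl_mesh_error")
})

test_that("gmsh and vtu writers emit well-formed files", {
  mesh <- build_mesh(kc_grid(), layers = 2, edge_central = 1.2,
                     edge_peripheral = 1.6)
  msh <- withr::local_tempfile(fileext = ".msh")
  write_msh(mesh, msh)
  lines <- readLines(msh)
  expect_equal(lines[which(lines == "$Nodes") + 1], as.character(nrow(mesh$nodes)))
  nel <- nrow(mesh$tets) + nrow(mesh$anterior_faces) + nrow(mesh$pressure_faces)
  expect_equal(lines[which(lines == "$Elements") + 1], as.character(nel))
  vtu <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh, vtu, point_data = list(dhat = mesh$dhat))
  doc <- xml2::read_xml(vtu)
  piece <- xml2::xml_find_first(doc, "//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(mesh$nodes))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               nrow(mesh$tets))
})
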