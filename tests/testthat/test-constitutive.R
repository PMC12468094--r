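# Depth profile and the fiber-reinforced hyperelastic law.

test_that("depth profile: anterior/posterior ratio 1.68, unit mean, linear", {
  expect_equal(depth_scale(0) / depth_scale(1), 1.68)
  expect_equal(integrate(depth_scale, 0, 1)$value, 1, tolerance = 1e-9)
  expect_equal(depth_scale(0.5), (depth_scale(0) + depth_scale(1)) / 2)
  expect_error(depth_scale(1.2), "depth")
  expect_equal(depth_scale(0, depth_ratio = 2) / depth_scale(1, depth_ratio = 2), 2)
})

test_that("undeformed state carries no stress", {
  r <- hgo_stress(diag(3), material_params())
  expect_lt(max(abs(r$S)), 1e-12)
  expect_equal(r$J, 1)
})

test_that("fiber stress scales exactly linearly in k1 (16.3x anchor)", {
  pm <- material_params()
  F <- diag(c(1.03, 1.02, 1 / (1.03 * 1.02)))
  s_full <- hgo_stress(F, pm)$S
  s_matrix <- hgo_stress(F, material_params(k1 = 0))$S
  s_cxl <- hgo_stress(F, material_params(k1 = 16.3 * pm$k1))$S
  fiber <- s_full - s_matrix
  expect_equal(s_cxl - s_matrix, 16.3 * fiber, tolerance = 1e-10)
})

test_that("stress matches the finite-difference gradient of the energy", {
  pm <- material_params()
  set.seed(7)
  for (rep in 1:3) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.01), 3, 3)
    r <- hgo_stress(F, pm)
    C <- t(F) %*% F
    W_of <- function(Cm) {
      e <- eigen(Cm, symmetric = TRUE)
      Fs <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
      hgo_stress(Fs, pm)$W
    }
    h <- 1e-6
    for (idx in list(c(1, 1), c(2, 2), c(1, 2))) {
      i <- idx[1]; j <- idx[2]
      Cp <- C; Cm <- C
      Cp[i, j] <- Cp[i, j] + h; Cm[i, j] <- Cm[i, j] - h
      if (i != j) { Cp[j, i] <- Cp[j, i] + h; Cm[j, i] <- Cm[j, i] - h }
      # S = 2 dW/dC: symmetric off-diagonal perturbation picks up S_ij once
      sfd <- (W_of(Cp) - W_of(Cm)) / (2 * h) * (if (i == j) 2 else 1)
      expect_lt(abs(sfd - r$S[i, j]) / max(abs(r$S)), 1e-5)
    }
  }
})

test_that("frame indifference: stress(QF) = Q stress(F) Q^T", {
  pm <- material_params()
  set.seed(11)
  F <- diag(3) + matrix(rnorm(9, 0, 0.02), 3, 3)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  s1 <- hgo_stress(q %*% F, pm)$sigma
  s0 <- hgo_stress(F, pm)$sigma
  expect_equal(s1, q %*% s0 %*% t(q), tolerance = 1e-10)
})

test_that("fibers are tension-only: equibiaxial compression equals matrix-only", {
  pm <- material_params()
  F <- diag(c(0.98, 0.98, 1 / 0.98^2))  # isochoric in-plane compression
  expect_equal(hgo_stress(F, pm)$S,
               hgo_stress(F, material_params(k1 = 0))$S, tolerance = 1e-14)
})

test_that("uniaxial stress is monotone over stretch 1.0-1.1 (convexity)", {
  pm <- material_params()
  lams <- seq(1.005, 1.1, length.out = 12)
  s11 <- vapply(lams, function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    hgo_stress(F, pm)$sigma[1, 1]
  }, 0)
  expect_true(all(diff(s11) > 0))
  expect_true(all(s11 > 0))
})

test_that("inverted deformation gradients are rejected", {
  expect_error(hgo_stress(diag(c(-1, 1, 1)), material_params()), "determinant")
})

test_that("material field composes depth, weakening and CXL multipliers", {
  mesh <- kc_mesh()
  pm <- material_params()
  wf <- kc_weakening()
  cf <- cxl_field(cxl_protocol("standard"), mesh, kc_cone())
  mf <- material_field(mesh, pm, weakening = wf, cxl = cf)
  s <- depth_scale(mf$qp_dhat, pm$depth_ratio)
  m_kc <- wf$fun(mf$qp_pos[, 1], mf$qp_pos[, 2])
  expect_equal(as.vector(t(mf$c_eff)), pm$c * s * m_kc, tolerance = 1e-12)
  # k1 = k1 * s * m_kc * m_cxl, all positive, cxl >= 1
  k1v <- as.vector(t(mf$k1_eff))
  expect_true(all(k1v >= pm$k1 * s * m_kc - 1e-9))
  expect_true(all(mf$c_eff > 0) && all(k1v > 0))
  # fiber directions are unit length and mutually orthogonal
  expect_equal(rowSums(mf$A1^2), rep(1, nrow(mf$A1)), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(mf$A1 * mf$A2))), 1e-12)
})
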