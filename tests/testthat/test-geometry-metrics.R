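# Keratometry: tangential curvature, Kmax metrics, biconic fitting, cone
# detection.

sphere_grid <- function(R, spacing = 0.1, diameter = 10) {
  generate_cornea(cornea_spec(r_flat = R, r_steep = R, q_flat = 0, q_steep = 0,
                              cone_amplitude = 0, cone_thinning = 0,
                              grid_spacing = spacing, grid_diameter = diameter))
}

test_that("exact spheres give exact tangential curvature", {
  for (R in c(7.5, 6.75)) {
    map <- tangential_curvature(sphere_grid(R))
    expect_true(all(map$valid))
    expect_equal(range(map$K_tg), rep(337.5 / R, 2), tolerance = 1e-8)
  }
})

test_that("curvature scale law: scaling coordinates by s scales K by 1/s", {
  pts <- grid_points(sphere_grid(7.5))
  k0 <- 337.5 / 7.5
  for (s in c(0.9, 1.1)) {
    map <- tangential_curvature(pts * s, neighborhood_radius = 0.12 * s)
    expect_equal(median(map$K_tg[map$valid]), k0 / s, tolerance = 1e-6)
  }
})

test_that("kmax metrics: constant field, mean <= max, planted bump location", {
  map <- tangential_curvature(sphere_grid(7.5))
  km <- kmax_metrics(map)
  expect_equal(km$kmax_t, 45, tolerance = 1e-8)
  expect_equal(km$kmaxmean3, 45, tolerance = 1e-8)
  kc <- kmax_metrics(kc_map())
  expect_lte(kc$kmaxmean3, kc$kmax_t)
  expect_lt(max(abs(kc$location - c(1, 0.5))), 0.1 + 1e-9)
})

test_that("biconic fit: exact recovery, degenerate sphere, keratometric formula", {
  fit <- fit_biconic(generate_cornea(cornea_spec(
    r_flat = 7.7, r_steep = 7.3, axis_flat = 0, q_flat = -0.2, q_steep = -0.2,
    cone_amplitude = 0, cone_thinning = 0)))
  expect_lt(abs(fit$R_flat - 7.7), 1e-3)
  expect_lt(abs(fit$R_steep - 7.3), 1e-3)
  # sphere = K_flat with index 1.376: R_flat 7.7 mm -> 48.8 D, the
  # population-mean keratometry scale the generator emulates
  expect_equal(fit$sphere, (1.376 - 1) / (1e-3 * fit$R_flat))
  expect_equal(round(fit$sphere, 1), 48.8)
  expect_equal(fit$cylinder, fit$K_steep - fit$K_flat)
  expect_equal(fit$spherical_equivalent, fit$sphere + fit$cylinder / 2)
  sph <- fit_biconic(sphere_grid(7.7))
  expect_lt(abs(sph$R_steep - 7.7), 1e-3)
  expect_lt(abs(sph$R_flat - 7.7), 1e-3)
  expect_equal(round(sph$cylinder, 2), 0)
})

test_that("rotation invariance: axis follows the rotation, radii unchanged", {
  spec <- cornea_spec(r_flat = 7.8, r_steep = 7.2, axis_flat = 20,
                      q_flat = -0.2, q_steep = -0.3,
                      cone_amplitude = 0, cone_thinning = 0)
  pts <- grid_points(generate_cornea(spec))
  fit0 <- fit_biconic(pts)
  phi <- 30 * pi / 180
  Rz <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
  fit1 <- fit_biconic(pts %*% t(Rz))
  expect_lt(abs(fit1$R_steep - fit0$R_steep) / fit0$R_steep, 5e-4)
  expect_lt(abs(fit1$R_flat - fit0$R_flat) / fit0$R_flat, 5e-4)
  dax <- (fit1$axis - fit0$axis - 30) %% 180
  expect_lt(min(dax, 180 - dax), 0.1)
  k0 <- kmax_metrics(tangential_curvature(pts))$kmax_t
  k1 <- kmax_metrics(tangential_curvature(pts %*% t(Rz)))$kmax_t
  expect_lt(abs(k1 - k0) / k0, 5e-4)
})

test_that("sphere <= spherical equivalent <= K_steep", {
  set.seed(4)
  for (i in 1:5) {
    rf <- runif(1, 7.4, 8.2)
    fit <- fit_biconic(generate_cornea(cornea_spec(
      r_flat = rf, r_steep = rf - runif(1, 0, 0.7),
      axis_flat = runif(1, 0, 179), cone_amplitude = 0, cone_thinning = 0)))
    expect_lte(fit$sphere, fit$spherical_equivalent + 1e-9)
    expect_lte(fit$spherical_equivalent, fit$K_steep + 1e-9)
    expect_gte(fit$cylinder, 0)
  }
})

test_that("biconic radii are recovered within 0.02 mm under 5 um noise", {
  errs <- vapply(1:50, function(i) {
    g <- generate_cornea(cornea_spec(cone_amplitude = 0, cone_thinning = 0,
                                     noise_sd = 5, seed = 1000L + i))
    fit <- fit_biconic(g)
    max(abs(fit$R_flat - 7.7), abs(fit$R_steep - 7.3))
  }, 0)
  expect_lt(max(errs), 0.02)
})

test_that("minimum pachymetry tie broken by radius then lexicographic order", {
  g <- generate_cornea(cornea_spec(central_thickness = 520, cone_thinning = 0,
                                   cone_amplitude = 0))
  mp <- min_pachymetry(g)
  expect_equal(mp$value, 520, tolerance = 1e-9)
  expect_equal(unname(mp$location), c(0, 0))
})

test_that("cone detection: member fraction, planted centre, empty-cone error", {
  cone <- kc_cone()
  n_central <- sum(kc_map()$valid &
                     (kc_map()$x^2 + kc_map()$y^2 <= 16))
  expect_lt(abs(length(cone$member_idx) - 0.325 * n_central), 2.5)
  expect_lt(max(abs(cone$center - c(1, 0.5))), 0.1 + 1e-9)
  expect_true(all(kc_map()$K_tg[cone$member_idx] > cone$threshold))
  expect_true(all(cone$normdist >= 0 & cone$normdist <= 1))
  expect_error(detect_cone(tangential_curvature(sphere_grid(7.5))),
               class = "cxl_empty_cone")
})
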