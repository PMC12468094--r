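# Keratoconus weakening ramp and CXL stiffening fields: printed anchors and
# continuity/monotonicity properties.

std_field <- function() cxl_field(cxl_protocol("standard"), kc_mesh(), kc_cone())
elza_field <- function() {
  fixture("elza_field", cxl_field(cxl_protocol("custom_elza"), kc_mesh(), kc_cone()))
}

test_that("standard field hits the printed anchors", {
  f <- std_field()$fun
  # peak multiplier at centre/surface
  expect_equal(f(0, 0, 0), 16.3)
  # radial weight 0.10 at 90% of the 4.5 mm zone radius
  r90 <- 0.9 * 4.5
  w <- (f(r90, 0, 0) - 1) / (16.3 - 1)
  expect_equal(w, 0.10, tolerance = 1e-12)
  expect_equal(f(r90, 0, 0), 1 + 15.3 * 0.10, tolerance = 1e-12)
  # no effect at (and below) 300 um depth
  expect_equal(f(0, 0, 300), 1)
  expect_equal(f(1.7, 0.4, 450), 1)
  # linear depth decay
  expect_equal(f(0, 0, 150), 1 + 15.3 * 0.5, tolerance = 1e-12)
})

test_that("custom-ELZA field: 1.33x peak, 400 um central depth, seam-free", {
  f <- elza_field()$fun
  cc <- kc_cone()$center
  expect_equal(f(cc[1], cc[2], 0), 1.33 * 16.3)
  # central zone still active between 300 and 400 um
  expect_gt(f(cc[1], cc[2], 350), 1)
  expect_equal(f(cc[1], cc[2], 400), 1)
  # pointwise >= standard field centred identically
  fs <- cxl_field(cxl_protocol("custom_standard"), kc_mesh(), kc_cone())$fun
  rs <- seq(0, 4.4, by = 0.05)
  for (d in c(0, 100, 250)) {
    expect_true(all(f(cc[1] + rs, cc[2], d) >= fs(cc[1] + rs, cc[2], d) - 1e-12))
  }
  # continuity: max relative jump at 0.02 mm sampling below 5%
  rs <- seq(0, 4.4, by = 0.02)
  v <- f(cc[1] + rs, cc[2], 50)
  expect_lt(max(abs(diff(v)) / v[-1]), 0.05)
})

test_that("fields are >= 1 and non-increasing in radius and depth", {
  for (fld in list(std_field(), elza_field())) {
    expect_true(all(fld$values >= 1 - 1e-12))
    f <- fld$fun
    ctr <- fld$params$center
    rs <- seq(0, 4, by = 0.1)
    for (d in c(0, 150)) {
      expect_true(all(diff(f(ctr[1] + rs, ctr[2], d)) <= 1e-12))
    }
    ds <- seq(0, 420, by = 20)
    expect_true(all(diff(f(ctr[1], ctr[2], ds)) <= 1e-12))
  }
})

test_that("K_CXL = 1 gives the no-treatment identity", {
  f <- cxl_field(cxl_protocol("standard", k_cxl = 1, elza_factor = 1),
                 kc_mesh(), kc_cone())
  expect_equal(range(f$values), c(1, 1))
})

test_that("custom protocols without a cone are rejected", {
  expect_error(cxl_field(cxl_protocol("custom_elza"), kc_mesh(), NULL),
               class = "cxl_field_error")
})

test_that("weakening field: 57% reduction at centre, linear ramp, identity", {
  wf <- kc_weakening()
  cc <- kc_cone()$center
  expect_equal(wf$fun(cc[1], cc[2]), 0.429)
  expect_equal(round((1 - wf$fun(cc[1], cc[2])) * 100), 57)
  # linear in normalized boundary distance: half way -> (0.429 + 1)/2
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ed <- vapply(th, function(a) {
    # walk out until the multiplier reaches 1 (field edge along this ray)
    rr <- seq(0.01, 4, by = 0.01)
    v <- wf$fun(cc[1] + rr * cos(a), cc[2] + rr * sin(a))
    rr[which(v >= 1 - 1e-9)[1]]
  }, 0)
  mid <- wf$fun(cc[1] + 0.5 * ed * cos(th), cc[2] + 0.5 * ed * sin(th))
  expect_equal(mid, rep((0.429 + 1) / 2, 8), tolerance = 0.02)
  expect_true(all(wf$values >= 0.429 - 1e-12 & wf$values <= 1 + 1e-12))
  # alpha = 1: healthy cornea
  wf1 <- weakening_field(kc_cone(), 1, kc_mesh())
  expect_equal(range(wf1$values), c(1, 1))
  # empty cone: warning and identity field
  expect_warning(wfe <- weakening_field(NULL, 0.429, kc_mesh()), "empty cone")
  expect_equal(range(wfe$values), c(1, 1))
})
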