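test_that("uniform fixture gives exact unit leakiness under both metrics", {
  fld <- analytic_field("uniform", branch_cell(2), U = 1.7)
  expect_identical(leakiness_gap_flux(fld)$Le, 1)
  expect_identical(leakiness_line(fld)$Le, 1)
  # arbitrary explicit line too
  ln <- list(from = c(0, 5, 0.5), to = c(0.25, 5, 3.5))
  expect_identical(leakiness_line(fld, line = ln)$Le, 1)
})

test_that("plane-channel line average recovers the parabolic 2/3 factor", {
  cl <- branch_cell(2)
  u0 <- 1.3
  fld <- analytic_field("plane_channel", cl, U = u0, parameters = list(u0 = u0),
                        n = c(64, 8, 8))
  # average over the full channel width of u0 (1 - xi^2), xi in [-1, 1], is
  # (2/3) u0; the default line spans the half-channel from axis to edge,
  # which has the same mean by symmetry
  le <- leakiness_line(fld, n = 4096)
  expect_equal(le$Le, 2 / 3, tolerance = 1e-3)
})

test_that("extruded potential flow has zero normal velocity on the cylinder", {
  cl <- branch_cell(2)
  fld <- analytic_field("extruded_potential_cylinder", cl, U = 2)
  ev <- attr(fld, "evaluate")
  th <- seq(0, 2 * pi, length.out = 181)
  R <- cl$diameter / 2
  pts <- cbind(cl$center_x + R * 1.0000001 * cos(th),
               cl$center_y + R * 1.0000001 * sin(th), 2)
  vel <- ev(pts)
  vn <- vel[, 1] * cos(th) + vel[, 2] * sin(th)
  expect_lt(max(abs(vn)), 1e-5)
  # far upstream the field tends to the free stream
  far <- ev(cbind(cl$center_x, 0.2, 2))
  expect_equal(as.numeric(far), c(0, 2, 0), tolerance = 2e-3)
})

test_that("fixture nodal values equal the closed form exactly", {
  cl <- branch_cell(2)
  fld <- analytic_field("linear_shear", cl, U = 0.5,
                        parameters = list(shear = 0.25), n = c(8, 10, 12))
  ev <- attr(fld, "evaluate")
  pts <- cbind(rep(fld$x[3], 12), fld$y[5], fld$z)
  expect_identical(as.numeric(fld$v[3, 5, ]), as.numeric(ev(pts)[, 2]))
})

test_that("trilinear interpolation is exact at nodes and on linear fields", {
  cl <- branch_cell(2)
  fld <- analytic_field("linear_shear", cl, U = 1,
                        parameters = list(shear = 0.4), n = c(12, 16, 20))
  # node reproduction
  p <- c(fld$x[5], fld$y[7], fld$z[9])
  expect_equal(as.numeric(interpolate_velocity(fld, p)),
               c(0, fld$v[5, 7, 9], 0), tolerance = 1e-14)
  # linear field: exact anywhere in the interior
  set.seed(5)
  pts <- cbind(runif(30, 0, cl$cell_width),
               runif(30, fld$y[1], fld$y[16]),
               runif(30, fld$z[1], fld$z[20]))
  got <- interpolate_velocity(fld, pts)
  expect_equal(got[, 2], 1 + 0.4 * pts[, 3], tolerance = 1e-12)
  # uniform field: edge midpoints give the uniform value
  uf <- analytic_field("uniform", cl, U = 3)
  mid <- c(mean(uf$x[1:2]), mean(uf$y[1:2]), uf$z[1])
  expect_equal(as.numeric(interpolate_velocity(uf, mid)), c(0, 3, 0))
  # out-of-domain in a non-periodic direction errors
  expect_error(interpolate_velocity(uf, c(0.1, -1, 2)), "outside")
  # periodic in x: wrap by the cell width changes nothing
  expect_equal(interpolate_velocity(fld, sweep(pts, 2, c(cl$cell_width, 0, 0), "+")),
               got, tolerance = 1e-12)
})

test_that("zero-velocity and zero-field leakiness metrics are exactly zero", {
  cl <- branch_cell(2)
  fld <- analytic_field("uniform", cl, U = 1)
  fld$u[] <- 0; fld$v[] <- 0; fld$w[] <- 0; fld$U <- 0
  expect_identical(leakiness_gap_flux(fld)$Le, 0)
  expect_identical(leakiness_line(fld)$Le, 0)
})
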