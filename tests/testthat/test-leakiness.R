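test_that("gap window and line sampling reject degenerate geometry", {
  cl <- branch_cell(2)
  fld <- analytic_field("uniform", cl, U = 1)
  # polyp tentacles reach into the gap window when the sampling plane sits
  # at the downstream tentacle tips
  fld$obstacles <- cell_obstacles(cl, polyp_model())
  expect_error(leakiness_gap_flux(fld, y_offset = 0.135), "intersects")
  # a line buried inside the cylinder cannot be averaged
  fld2 <- analytic_field("uniform", cl, U = 1)
  fld2$obstacles <- cell_obstacles(cl)
  ln <- list(from = c(cl$center_x, cl$center_y, 2),
             to = c(cl$center_x + 0.04, cl$center_y, 2))
  expect_error(leakiness_line(fld2, line = ln), "inside")
})

test_that("axis-to-edge averaging counts solid samples as zero velocity", {
  cl <- branch_cell(2)
  fld <- analytic_field("uniform", cl, U = 2)
  fld$obstacles <- cell_obstacles(cl)
  # uniform flow outside the cylinder: fluid fraction of the line is
  # 1 - (D/2) / (cell_width/2) = 2/3, so the axis-mode average is 2/3
  le <- leakiness_line(fld, n = 3000)
  expect_equal(le$Le, 2 / 3, tolerance = 2e-3)
  # surface mode averages the fluid portion only
  le_s <- leakiness_line(fld, from = "surface", n = 3000)
  expect_equal(le_s$Le, 1, tolerance = 1e-6)
})

test_that("a single-point sweep equals the solve-and-measure composition", {
  # identity check only: a deliberately early-stopped deterministic solve
  # keeps this fast; physical convergence is covered elsewhere
  settings <- fast_settings(max_iter = 60L, tol = 1e30, cascade = FALSE)
  sw <- leakiness_sweep("branch", g_over_d = 1, U = 0.5, settings = settings)
  expect_s3_class(sw, "leakiness_sweep")
  fld <- quiet_solve(branch_cell(1), 0.5, settings = settings)
  expect_equal(sw$Le_gap[1], leakiness_gap_flux(fld)$Le, tolerance = 1e-12)
  expect_equal(sw$Le_line[1], leakiness_line(fld)$Le, tolerance = 1e-12)
  expect_equal(sw$Re_nominal[1], 5)
})

test_that("sweep records solver failures without aborting", {
  sw <- leakiness_sweep("branch", g_over_d = 1, U = c(-1, 0.5),
                        settings = fast_settings(max_iter = 80L, tol = 1e-12,
                                                 cascade = FALSE))
  expect_equal(nrow(sw), 2)
  expect_false(anyNA(sw$error))
  expect_true(all(is.na(sw$Le_gap)))
})
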