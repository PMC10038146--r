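# Solver-backed tests use the scaled-down mini cell from the helper so each
# solve takes seconds; full-size cells are exercised in the acceptance suite.

test_that("an empty obstacle set yields the uniform stream exactly", {
  cl <- mini_cell(1)
  obs <- cell_obstacles(cl)
  obs$solids <- list()
  fld <- solve_steady(cl, 0.7, obstacles = obs,
                      settings = fast_settings(cascade = FALSE))
  expect_identical(max(abs(fld$u)), 0)
  expect_identical(max(abs(fld$w)), 0)
  expect_equal(max(abs(fld$v - 0.7)), 0, tolerance = 1e-12)
  expect_true(fld$convergence$converged)
  expect_lt(fld$convergence$iterations, 200)
})

test_that("zero inlet speed gives an identically zero unsteady field", {
  fld <- solve_unsteady(mini_cell(1), 0, settings = fast_settings())
  expect_identical(max(abs(fld$u)), 0)
  expect_identical(max(abs(fld$v)), 0)
  expect_identical(max(abs(fld$w)), 0)
  expect_identical(leakiness_gap_flux(fld)$Le, 0)
})

test_that("a converged solve conserves mass and kills velocity in solids", {
  fld <- mini_field(1, 0.5)
  expect_true(fld$convergence$converged)
  expect_lt(fld$convergence$residual, 1e-4)
  # streamwise volumetric flux equals the inlet flux through every section
  expect_lt(fld$convergence$flux_spread, 0.03)
  expect_equal(fld$convergence$flux_inlet,
               0.5 * fld$cell$cell_width * fld$cell$domain_height,
               tolerance = 1e-6)
  # effective discrete divergence within the documented tolerance
  expect_lt(fld$convergence$max_divergence, 1e-3)
  # no-slip masking: velocity samples inside the solid are zero
  solid <- fld$mask == 1L
  expect_gt(sum(solid), 0)
  expect_identical(max(abs(fld$u[solid])), 0)
  expect_identical(max(abs(fld$v[solid])), 0)
  expect_identical(max(abs(fld$w[solid])), 0)
})

test_that("full-domain solution is symmetric about the z mid-plane", {
  fld <- quiet_solve(mini_cell(1), 0.5,
                     settings = fast_settings(half_domain = FALSE))
  nz <- length(fld$z)
  vtop <- fld$v[, , nz:1]
  scale <- max(abs(fld$v))
  expect_lt(max(abs(fld$v - vtop)) / scale, 0.02)
  wtop <- fld$w[, , nz:1]
  expect_lt(max(abs(fld$w + wtop)) / scale, 0.02)
  # and it agrees with the half-domain (mirrored) solution
  half <- mini_field(1, 0.5)
  expect_equal(leakiness_gap_flux(fld)$Le, leakiness_gap_flux(half)$Le,
               tolerance = 0.02)
})

test_that("gap-flux leakiness increases with inlet speed at fixed geometry", {
  le <- vapply(c(0.25, 0.5, 1.0), function(U)
    leakiness_gap_flux(mini_field(1, U))$Le, numeric(1))
  expect_true(all(diff(le) > 0))
  expect_true(all(le > 0 & le < 1.5))
})

test_that("non-convergence raises a structured error with residual history", {
  err <- tryCatch(
    solve_steady(mini_cell(1), 0.5,
                 settings = fast_settings(max_iter = 30L, tol = 1e-12,
                                          cascade = FALSE)),
    error = function(e) e)
  expect_s3_class(err, "gorgflow_convergence_error")
  expect_gt(length(err$residual_history), 0)
})

test_that("solver settings are validated and high Re draws a regime warning", {
  expect_error(solver_settings(resolution = 4), "at least 8")
  expect_error(solver_settings(tol = -1))
  expect_warning(
    try(solve_steady(branch_cell(2), 50,
                     settings = fast_settings(max_iter = 1L, tol = 1e30,
                                              cascade = FALSE)),
        silent = TRUE),
    "exceeds ~200")
})

test_that("drag from the momentum deficit is resolution-consistent", {
  # Richardson-style self-oracle: the control-volume drag at 8 and 12
  # cells per diameter agrees within 10% at Re of order 1
  f8 <- mini_field(1, 0.5)
  f12 <- quiet_solve(mini_cell(1), 0.5,
                     settings = fast_settings(resolution = 12))
  d8 <- drag_force(f8)$force_per_span
  d12 <- drag_force(f12)$force_per_span
  expect_gt(d8, 0)
  expect_lt(abs(d12 - d8) / d12, 0.10)
  # and the gap-flux leakiness moves by less than 5% under the same refinement
  le8 <- leakiness_gap_flux(f8)$Le
  le12 <- leakiness_gap_flux(f12)$Le
  expect_lt(abs(le12 - le8) / le8, 0.05)
})
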