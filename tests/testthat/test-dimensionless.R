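test_that("Reynolds numbers match hand calculations under both conventions", {
  # rho L U / mu with seawater constants
  expect_equal(as.numeric(reynolds(0.1, 100)), 1.025 * 0.1 * 100 / 0.0108,
               tolerance = 1e-12)
  expect_equal(round(as.numeric(reynolds(0.1, 100)), 1), 949.1)
  # nominal labelling: 0.1 cm branch at 0.2 cm/s is Re = 2 exactly
  expect_equal(as.numeric(reynolds(0.1, 0.2, convention = "nominal")), 2)
  expect_identical(as.numeric(reynolds(0.1, 0, convention = "nominal")), 0)
  expect_identical(attr(reynolds(1, 1), "convention"), "true")
})

test_that("Peclet numbers reproduce the branch-level feeding values", {
  d <- diffusivities()
  expect_equal(peclet(0.1, 0.8, d[["plankton"]]), 32)
  expect_equal(peclet(0.1, 0.1, d[["plankton"]]), 4)
  expect_identical(peclet(0.1, 0, d[["plankton"]]), 0)
})

test_that("Re and Pe are linear in L and U; Pe ratios invert diffusivities", {
  d <- diffusivities()
  for (L in c(0.02, 0.1, 1)) {
    for (U in c(0.3, 2)) {
      expect_equal(as.numeric(reynolds(2 * L, U)), 2 * as.numeric(reynolds(L, U)))
      expect_equal(peclet(L, 2 * U, d[[1]]), 2 * peclet(L, U, d[[1]]))
      # Pe_a / Pe_b = d_b / d_a exactly at fixed L, U
      expect_equal(peclet(L, U, d[["plankton"]]) / peclet(L, U, d[["O2"]]),
                   d[["O2"]] / d[["plankton"]])
    }
  }
})

test_that("porosity coefficient follows Lambda = Le F / U", {
  expect_equal(porosity_coefficient(0, 3, 2)$Lambda, 0)
  expect_equal(porosity_coefficient(1, 4, 4)$Lambda, 1)
  expect_equal(porosity_coefficient(0.5, 2, 4)$Lambda, 0.25)
  expect_error(porosity_coefficient(0.5, 2, 0))
})

test_that("morphometric summaries compute per-specimen ratio statistics", {
  expect_equal(morphometric_summary(data.frame(gap = 0.2, diameter = 0.1))$gd_mean, 2)
  dup <- data.frame(specimen = "a", gap = c(0.2, 0.2), diameter = c(0.1, 0.1),
                    height = c(1, 1))
  s <- morphometric_summary(dup)
  expect_equal(s$gd_sd, 0)
  expect_equal(s$hd_mean, 10)
  expect_equal(s$hd_sd, 0)
  expect_error(morphometric_summary(data.frame(gap = -1, diameter = 1)))
  mixed <- data.frame(specimen = "a", gap = c(1, 1), diameter = c(2, 2),
                      unit = c("cm", "px"))
  expect_error(morphometric_summary(mixed), "units")
})

test_that("synthetic morphometric tables stay inside the published ranges", {
  for (seed in c(1, 99)) {
    tb <- morphometric_table(8, "branch", seed = seed)
    s <- morphometric_summary(tb)
    expect_true(all(s$gd_mean >= 1.3 & s$gd_mean <= 4))
    expect_true(all(s$hd_mean >= 4.5 & s$hd_mean <= 30))
    tp <- morphometric_table(6, "pinnule", seed = seed)
    expect_true(all(tp$gap / tp$diameter >= 1.25 & tp$gap / tp$diameter <= 2.5))
    tt <- morphometric_table(6, "tentacle", seed = seed)
    expect_true(all(tt$gap / tt$diameter >= 1.75 & tt$gap / tt$diameter <= 3))
  }
  expect_identical(morphometric_table(5, "branch", seed = 3),
                   morphometric_table(5, "branch", seed = 3))
})

test_that("dimensionless report tabulates Re and Pe per level", {
  rep <- dimensionless_report(data.frame(level = "branch", L = 0.1, U = 0.8))
  expect_equal(rep$Re_nominal, 8)
  expect_equal(rep$Pe_plankton, 32)
  expect_equal(rep$Re_true, 0.08 / fluid_properties()$kinematic_viscosity)
})
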