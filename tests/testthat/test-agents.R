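# Transport tests run on analytic fixture fields so no solver is needed.

uniform_cylinder_field <- function(U = 0.8, g_over_d = 2, tiles_to = 3.6) {
  fld <- analytic_field("uniform", branch_cell(g_over_d), U = U)
  fld$obstacles <- cell_obstacles(branch_cell(g_over_d))
  tile_field(fld, tiles_to)
}

test_that("tiling arithmetic follows the cell width", {
  fld <- analytic_field("uniform", branch_cell(1), U = 1)  # width 0.2
  expect_identical(tile_field(fld, 3.6)$tiles, 18L)
  fld9 <- analytic_field("uniform", branch_cell(8), U = 1) # width 0.9
  expect_identical(tile_field(fld9, 3.6)$tiles, 4L)
  expect_error(tile_field(fld9, 0.2), "narrower")
  # periodicity: velocity lookups repeat across tiles
  sfld <- analytic_field("plane_channel", branch_cell(2), U = 1)
  p <- c(0.11, 3, 1.9)
  expect_equal(interpolate_velocity(sfld, p),
               interpolate_velocity(sfld, p + c(0.3, 0, 0)), tolerance = 1e-12)
})

test_that("agents stay put in a zero field with zero variance", {
  fld <- tile_field(analytic_field("uniform", branch_cell(2), U = 0), 3.6)
  fld$U <- 1  # avoid division anywhere; velocities are all zero
  params <- agent_params(n_agents = 50, motion_variance = 0, dt = 0.01)
  ens <- init_agents(params, seed = 11)
  out <- step_agents(ens, fld, params, n_steps = 25)
  expect_identical(out$positions, ens$positions)
  expect_identical(out$status, ens$status)
  expect_equal(out$time, 0.25)
})

test_that("Brownian displacement variance grows as variance * time", {
  fld <- tile_field(analytic_field("uniform", branch_cell(2), U = 0), 3.6)
  n <- 2500
  params <- agent_params(n_agents = n, motion_variance = 2.5e-3, dt = 0.01)
  ens <- init_agents(params, seed = 1)
  ens$positions[, 1] <- 1.8
  ens$positions[, 2] <- 5
  ens$positions[, 3] <- 2
  nsteps <- 200
  out <- step_agents(ens, fld, params, n_steps = nsteps, seed = 202)
  t <- nsteps * params$dt
  target <- params$motion_variance * t
  for (ax in 1:3) {
    disp <- out$positions[, ax] - ens$positions[, ax]
    v <- mean(disp^2)
    # chi-square sampling band for n independent Gaussians, ~4 sigma wide
    expect_gt(v, target * (1 - 4 * sqrt(2 / n)))
    expect_lt(v, target * (1 + 4 * sqrt(2 / n)))
  }
  expect_true(all(out$status == 0L))
  # same seed reproduces bit for bit
  again <- step_agents(ens, fld, params, n_steps = nsteps, seed = 202)
  expect_identical(again$positions, out$positions)
})

test_that("capture fraction matches the geometric shadow for straight advection", {
  # uniform flow, no Brownian motion, agents released on a sheet spanning
  # exactly 10 cells: the captured fraction is the cylinder shadow
  # (D / cell_width) * (H / sheet z-extent)
  fld <- uniform_cylinder_field(U = 0.8)
  params <- agent_params(n_agents = 1000, motion_variance = 0, dt = 0.01,
                         sheet = c(0.3, 3.3, 1.0, 0.6, 3.4))
  p_exact <- (0.1 / 0.3) * (1 / 2.8)
  fr <- numeric(5)
  for (r in seq_len(5)) {
    ens <- init_agents(params, seed = 100 + r)
    out <- step_agents(ens, fld, params, n_steps = 1500, seed = 300 + r)
    expect_identical(sum(out$status == 0L) +
                     sum(out$status == 1L) + sum(out$status == 2L),
                     params$n_agents)
    fr[r] <- mean(out$status == 1L)
  }
  se <- sqrt(p_exact * (1 - p_exact) / (5 * params$n_agents))
  expect_lt(abs(mean(fr) - p_exact), 4 * se + 1e-3)
})

test_that("capture fraction is invariant to the number of tiles", {
  params <- agent_params(n_agents = 800, motion_variance = 2.5e-3, dt = 0.01,
                         sheet = c(0.3, 1.5, 1.0, 0.6, 3.4))
  frac <- function(target_width, seed) {
    fld <- uniform_cylinder_field(tiles_to = target_width)
    ens <- init_agents(params, seed = seed)
    out <- step_agents(ens, fld, params, n_steps = 1500, seed = seed + 7)
    mean(out$status == 1L)
  }
  f12 <- vapply(1:3, function(s) frac(3.6, s), numeric(1))
  f6 <- vapply(4:6, function(s) frac(1.8, s), numeric(1))
  expect_lt(abs(mean(f12) - mean(f6)),
            3 * sqrt(var(c(f12, f6)) / 3) + 0.02)
})

test_that("segment capture detection is continuous and exact on cylinders", {
  obs <- cell_obstacles(branch_cell(2))
  cl <- obs$cell
  mid <- (cl$z0 + cl$z1) / 2
  # wholly outside
  expect_false(detect_capture(c(0.01, 1, mid), c(0.01, 3, mid), obs)$captured)
  # outside to center: first contact on the surface
  hit <- detect_capture(c(cl$center_x - 0.25, cl$center_y, mid),
                        c(cl$center_x, cl$center_y, mid), obs)
  expect_true(hit$captured)
  expect_equal(hit$contact, c(cl$center_x - 0.05, cl$center_y, mid),
               tolerance = 1e-9)
  # crossing straight through (both endpoints outside) still captures
  expect_true(detect_capture(c(cl$center_x, 1.8, mid),
                             c(cl$center_x, 2.2, mid), obs)$captured)
  # capture through a periodic image
  expect_true(detect_capture(c(cl$center_x + cl$cell_width, 1.8, mid),
                             c(cl$center_x + cl$cell_width, 2.2, mid),
                             obs)$captured)
  # entering through the top cap
  expect_true(detect_capture(c(cl$center_x, cl$center_y, cl$z1 + 0.1),
                             c(cl$center_x, cl$center_y, cl$z1 - 0.1),
                             obs)$captured)
})

test_that("grazing segments agree with a dense subdivision oracle", {
  obs <- cell_obstacles(branch_cell(2), polyp_model())
  cl <- obs$cell
  set.seed(31)
  n_checked <- 0
  for (trial in 1:40) {
    from <- c(runif(1, 0.05, 0.25), runif(1, 1.85, 2.0), runif(1, 1.5, 2.5))
    to <- from + c(runif(1, -0.08, 0.08), runif(1, 0.05, 0.2),
                   runif(1, -0.08, 0.08))
    got <- detect_capture(from, to, obs)$captured
    ts <- seq(0, 1, length.out = 4001)
    pts <- cbind(from[1] + ts * (to[1] - from[1]),
                 from[2] + ts * (to[2] - from[2]),
                 from[3] + ts * (to[3] - from[3]))
    oracle <- min(locate(pts, obs)$distance)
    # skip knife-edge cases the finite oracle cannot classify
    if (abs(oracle) < 1e-5) next
    expect_identical(got, oracle <= 0)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 25)
})

test_that("agent parameter validation and dt warning work", {
  expect_error(agent_params(dt = 0), "dt")
  params <- agent_params(n_agents = 10, motion_variance = 0, dt = 1)
  fld <- uniform_cylinder_field(U = 0.8)  # step 0.8 cm > D/2
  ens <- init_agents(params, seed = 1)
  expect_warning(step_agents(ens, fld, params, 1), "D/2")
})

test_that("halving dt leaves the mean capture fraction within replicate noise", {
  fld <- uniform_cylinder_field(U = 0.8)
  frac_at <- function(dt, seeds) {
    vapply(seeds, function(s) {
      p <- agent_params(n_agents = 600, motion_variance = 2.5e-3, dt = dt,
                        sheet = c(0.3, 3.3, 1.0, 0.6, 3.4))
      out <- step_agents(init_agents(p, seed = s), fld, p,
                         n_steps = as.integer(13 / dt), seed = s + 50)
      mean(out$status == 1L)
    }, numeric(1))
  }
  f1 <- frac_at(0.01, 1:4)
  f2 <- frac_at(0.005, 5:8)
  expect_lt(abs(mean(f1) - mean(f2)), sd(c(f1, f2)) + 0.01)
})
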