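test_that("cell constructors reproduce the published domain widths", {
  # branch: width 0.15-0.9 cm over the simulated gap-ratio range
  expect_equal(branch_cell(0.5)$cell_width, 0.15)
  expect_equal(branch_cell(8)$cell_width, 0.9)
  expect_equal(branch_cell(1)$cell_width, 0.2)
  # tentacle: 0.0625-0.1 cm
  expect_equal(tentacle_cell(1.5)$cell_width, 0.0625)
  expect_equal(tentacle_cell(3)$cell_width, 0.1)
  expect_equal(tentacle_cell(2)$cell_width, 0.075)
  # pinnule: 0.05625-0.0875 mm, stored in cm
  expect_equal(pinnule_cell(1.25)$cell_width, 0.005625)
  expect_equal(pinnule_cell(2.5)$cell_width, 0.00875)
  expect_equal(pinnule_cell(2)$cell_width, 0.0075)
})

test_that("cell invariants hold across constructors and ratios", {
  for (make in list(branch_cell, tentacle_cell, pinnule_cell)) {
    for (g in c(1, 1.5, 2, 3, 4.5)) {
      cl <- make(g)
      expect_identical(cl$cell_width - (cl$diameter + cl$gap), 0)
      expect_lt(cl$cell_width, cl$domain_length)
      expect_lt(cl$height, cl$domain_height)
      # geometric similarity: 100 D long, 40 D high, cylinder 20 D downstream
      expect_equal(cl$domain_length / cl$diameter, 100)
      expect_equal(cl$domain_height / cl$diameter, 40)
      expect_equal(cl$inlet_offset / cl$diameter, 20)
      expect_equal(cl$height / cl$diameter, 10)
    }
  }
  expect_error(branch_cell(-1), "g_over_d")
  expect_error(branch_cell(0), "g_over_d")
  expect_error(tentacle_cell(0.5), "g_over_d")
  expect_error(pinnule_cell(9), "g_over_d")
})

test_that("fluid properties are consistent and validated", {
  fl <- fluid_properties()
  expect_equal(fl$kinematic_viscosity, fl$dynamic_viscosity / fl$density)
  expect_error(fluid_properties(density = -1))
})

test_that("polyp-decorated obstacle set has the expected structure", {
  cl <- branch_cell(2)
  obs <- cell_obstacles(cl, polyp_model())
  # 1 cylinder + 8 polyps x (1 stalk + 8 tentacles)
  expect_length(obs$solids, 73)
  expect_true(obs$has_polyps)
  # degenerate: no polyps reduces to the plain cylinder
  obs0 <- cell_obstacles(cl, polyp_model(polyps_per_side = 0))
  expect_length(obs0$solids, 1)
  # total polyp reach from the branch surface is the modelled height
  pm <- polyp_model()
  expect_equal(pm$stalk_length + pm$tentacle_length * cospi(pm$splay_angle / 180),
               pm$polyp_height)
  # oversized tentacles must collide with the periodic images
  expect_error(
    cell_obstacles(cl, polyp_model(tentacle_length = 0.35, polyp_height = 0.4)),
    "periodic")
})

test_that("signed distance queries match closed forms", {
  cl <- branch_cell(2)
  obs <- cell_obstacles(cl)
  ax <- c(cl$center_x, cl$center_y)
  mid <- (cl$z0 + cl$z1) / 2
  res <- locate(rbind(
    c(ax, mid),                          # center: inside, -D/2
    c(ax[1] + cl$diameter, ax[2], mid),  # D from axis: outside, +D/2
    c(ax, cl$z1 + 0.37)                  # above the tip on the axis
  ), obs)
  expect_equal(res$inside, c(TRUE, FALSE, FALSE))
  expect_equal(res$distance, c(-0.05, 0.05, 0.37))
})

test_that("distance above the tip agrees with brute-force surface sampling", {
  cl <- branch_cell(2)
  obs <- cell_obstacles(cl)
  p <- c(cl$center_x + 0.02, cl$center_y - 0.01, cl$z1 + 0.2)
  # dense sampling of the cylinder surface (shell + caps)
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  zs <- seq(cl$z0, cl$z1, length.out = 401)
  shell <- cbind(rep(cl$center_x + 0.05 * cos(th), length(zs)),
                 rep(cl$center_y + 0.05 * sin(th), length(zs)),
                 rep(zs, each = length(th)))
  rr <- seq(0, 0.05, length.out = 101)
  cap <- cbind(cl$center_x + rep(rr, each = length(th)) * cos(th),
               cl$center_y + rep(rr, each = length(th)) * sin(th),
               cl$z1)
  surf <- rbind(shell, cap)
  brute <- sqrt(min(colSums((t(surf) - p)^2)))
  expect_equal(locate(p, obs)$distance, brute, tolerance = 1e-4)
})

test_that("locate is invariant under periodic wrap", {
  cl <- branch_cell(1.5)
  obs <- cell_obstacles(cl, polyp_model())
  set.seed(42)
  pts <- cbind(runif(40, 0, cl$cell_width),
               runif(40, 1.7, 2.3),
               runif(40, 1.2, 2.8))
  base <- locate(pts, obs)
  for (shift in c(-2, 1, 5)) {
    moved <- pts
    moved[, 1] <- moved[, 1] + shift * cl$cell_width
    expect_equal(locate(moved, obs), base, tolerance = 1e-12)
  }
})

test_that("polyp obstacle set is symmetric under z reflection", {
  cl <- branch_cell(2)
  obs <- cell_obstacles(cl, polyp_model())
  zmid <- cl$domain_height / 2
  set.seed(7)
  pts <- cbind(runif(60, 0, cl$cell_width), runif(60, 1.7, 2.4),
               runif(60, 1.3, 2))
  mirr <- pts
  mirr[, 3] <- 2 * zmid - mirr[, 3]
  expect_equal(locate(pts, obs)$distance, locate(mirr, obs)$distance,
               tolerance = 1e-12)
  # and under x reflection through the cylinder axis
  mirx <- pts
  mirx[, 1] <- 2 * cl$center_x - mirx[, 1]
  expect_equal(locate(pts, obs)$distance, locate(mirx, obs)$distance,
               tolerance = 1e-12)
})
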