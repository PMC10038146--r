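#' Flow solver settings
#'
#' Numerical controls for [solve_steady()] and [solve_unsteady()]. The solver
#' uses an artificial-compressibility finite-volume scheme on a graded
#' staggered grid, with local pseudo-time stepping for steady solves and a
#' global stable time step for time-marched solves. Lengths below are in
#' units of the cylinder diameter D.
#'
#' @param resolution cells per diameter in the refined region (>= 8).
#' @param tol steady convergence tolerance on the normalized momentum
#'   residual (RMS du/dtau over the velocity scale).
#' @param max_iter maximum pseudo-time iterations.
#' @param cfl pseudo-time CFL number.
#' @param mode `"steady"` or `"unsteady"`.
#' @param total_time physical time horizon for unsteady solves, seconds;
#'   default 5 domain flow-through times.
#' @param half_domain exploit the z mid-plane symmetry of the geometry and
#'   solve only the lower half (mirrored on return). Disabled automatically
#'   when the obstacle set is not symmetric.
#' @param far_spacing far-field target spacings `c(y, z)` in diameters.
#' @param body_spacing target spacing along the cylinder shaft (z), diameters.
#' @param grade_slope growth rate of cell size away from refined windows.
#' @param mask_inflate sub-grid solids are inflated to this fraction of the
#'   local cell size when rasterized, so thin polyp tentacles still block
#'   at least one cell.
#' @param divergence_tol acceptable relative divergence (|div u| D / U) in
#'   fluid cells of a converged solution.
#' @param cascade warm-start the steady solve from a converged half-resolution
#'   solution of the same problem (full multigrid-style cascade); cuts wall
#'   time substantially without changing the converged answer.
#' @param check_every residual check interval, iterations.
#' @param verbose print residuals while iterating.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(resolution = 8, tol = 1e-4, max_iter = 60000L,
                            cfl = 0.9, mode = c("steady", "unsteady"),
                            total_time = NULL, half_domain = TRUE,
                            far_spacing = c(6, 4), body_spacing = 0.5,
                            grade_slope = 0.5, mask_inflate = 0.5,
                            divergence_tol = 1e-3, cascade = TRUE,
                            check_every = 100L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (resolution < 8) {
    stop("`resolution` must be at least 8 cells per diameter", call. = FALSE)
  }
  stopifnot(tol > 0, max_iter >= 1, cfl > 0, cfl <= 1.2)
  structure(list(
    resolution = resolution, tol = tol, max_iter = as.integer(max_iter),
    cfl = cfl, mode = mode, total_time = total_time,
    half_domain = isTRUE(half_domain),
    far_spacing = far_spacing, body_spacing = body_spacing,
    grade_slope = grade_slope, mask_inflate = mask_inflate,
    divergence_tol = divergence_tol, cascade = isTRUE(cascade),
    check_every = as.integer(check_every), verbose = isTRUE(verbose)
  ), class = "solver_settings")
}

# Graded 1-d cell widths: fine spacing inside the given windows, growing
# linearly with distance outside, capped at h_far; rescaled to fit exactly.
graded_axis <- function(total, windows, h_far, slope = 0.45) {
  hfun <- function(y) {
    h <- h_far
    if (length(windows)) {
      for (r in seq_len(nrow(windows))) {
        d <- max(windows[r, 1] - y, y - windows[r, 2], 0)
        h <- min(h, windows[r, 3] + slope * d)
      }
    }
    h
  }
  pos <- 0
  hs <- numeric(0)
  repeat {
    h <- hfun(pos)
    hs <- c(hs, h)
    pos <- pos + h
    if (pos >= total) break
    if (length(hs) > 1e5) stop("grid generation runaway", call. = FALSE)
  }
  hs * (total / sum(hs))
}

# solids of an obstacle set as plain matrices (for the C++ kernels),
# optionally rescaled by 1/scale
solids_matrices <- function(obstacles, scale = 1) {
  cyl <- cap <- NULL
  for (s in obstacles$solids) {
    if (s$type == "cylinder") {
      cyl <- rbind(cyl, c(s$center, s$radius, s$z0, s$z1) / scale)
    } else {
      cap <- rbind(cap, c(s$p0, s$p1, s$radius) / scale)
    }
  }
  list(
    cyl = if (is.null(cyl)) matrix(0, 0, 5) else cyl,
    cap = if (is.null(cap)) matrix(0, 0, 7) else cap
  )
}

# is the obstacle set symmetric about the domain z mid-plane?
obstacles_z_symmetric <- function(obstacles, zmid, tol = 1e-9) {
  mirror <- function(s) {
    if (s$type == "cylinder") {
      s[c("z0", "z1")] <- list(2 * zmid - s$z1, 2 * zmid - s$z0)
    } else {
      p0 <- s$p0; p1 <- s$p1
      p0[3] <- 2 * zmid - p0[3]; p1[3] <- 2 * zmid - p1[3]
      s$p0 <- p0; s$p1 <- p1
    }
    s
  }
  key <- function(s) {
    v <- if (s$type == "cylinder") c(1, s$center, s$radius, s$z0, s$z1, 0, 0)
         else c(2, sort(c(s$p0[3], s$p1[3])), s$p0[1:2], s$p1[1:2], s$radius)
    paste(sprintf("%.9f", round(v / tol) * tol), collapse = ",")
  }
  k1 <- sort(vapply(obstacles$solids, key, character(1)))
  k2 <- sort(vapply(lapply(obstacles$solids, mirror), key, character(1)))
  identical(k1, k2)
}

# Build the nondimensional grid (units of D) for a cell + obstacle set.
# Returns x/y/z cell widths and centers, the half-domain flag actually used,
# and the solid mask.
cell_grid <- function(cell, obstacles, settings) {
  D <- cell$diameter
  hf <- 1 / settings$resolution
  L <- cell$domain_length / D
  Hz <- cell$domain_height / D
  w <- cell$cell_width / D
  yc_cyl <- cell$inlet_offset / D
  z0 <- cell$z0 / D
  z1 <- cell$z1 / D
  zmid <- Hz / 2

  # at least `resolution` cells across the diameter AND across the gap:
  # narrow gaps (G/D < 1) are the regions that decide leakiness and capture
  g <- cell$g_over_d
  nx <- max(8L, as.integer(round(w / hf)),
            as.integer(ceiling(settings$resolution * (1 + g) / g)))
  dx <- w / nx

  # streamwise refinement window covers the obstacles plus wake onset
  sm <- solids_matrices(obstacles, scale = D)
  yext <- c(yc_cyl - 0.5, yc_cyl + 0.5)
  if (nrow(sm$cap)) {
    yext <- range(yext, sm$cap[, 2] - sm$cap[, 7], sm$cap[, 2] + sm$cap[, 7],
                  sm$cap[, 5] - sm$cap[, 7], sm$cap[, 5] + sm$cap[, 7])
  }
  ywin <- matrix(c(yext[1] - 0.7, yext[2] + 2, hf), 1)
  dy <- graded_axis(L, ywin, settings$far_spacing[1], settings$grade_slope)

  half <- settings$half_domain && obstacles_z_symmetric(obstacles, cell$domain_height / 2)
  body_h <- if (nrow(sm$cap)) hf else settings$body_spacing
  # build the lower half and mirror, so full-domain grids are exactly
  # symmetric about the mid-plane
  zwin <- rbind(c(z0 - 0.8, z0 + 1.2, hf),
                c(z0 + 1.2, zmid, body_h))
  zwin <- zwin[zwin[, 2] > zwin[, 1], , drop = FALSE]
  dz <- graded_axis(zmid, zwin, settings$far_spacing[2], settings$grade_slope)
  if (!half) dz <- c(dz, rev(dz))

  xc <- (seq_len(nx) - 0.5) * dx
  yc <- cumsum(dy) - dy / 2
  zc <- cumsum(dz) - dz / 2

  mask <- gf_mask_cells(xc, yc, zc, rep(dx, nx), dy, dz, w,
                        sm$cyl, sm$cap, settings$mask_inflate)
  list(nx = nx, dx = dx, dy = dy, dz = dz, xc = xc, yc = yc, zc = zc,
       mask = mask, half = half, w = w, L = L, Hz = Hz, sm = sm)
}

# mirror a half-domain solution into the full domain
mirror_field <- function(arr, nx, ny, nzh, flip_sign = FALSE) {
  a <- array(arr, dim = c(nx, ny, nzh))
  full <- array(0, dim = c(nx, ny, 2 * nzh))
  full[, , seq_len(nzh)] <- a
  full[, , nzh + seq_len(nzh)] <- (if (flip_sign) -1 else 1) * a[, , rev(seq_len(nzh))]
  full
}

finish_field <- function(sol, g, cell, obstacles, U, fluid, settings, mode) {
  D <- cell$diameter
  nx <- g$nx
  ny <- length(g$dy)
  nzh <- length(g$dz)
  if (g$half) {
    u <- mirror_field(sol$u, nx, ny, nzh)
    v <- mirror_field(sol$v, nx, ny, nzh)
    w <- mirror_field(sol$w, nx, ny, nzh, flip_sign = TRUE)
    p <- mirror_field(sol$p, nx, ny, nzh)
    mask <- mirror_field(sol$mask, nx, ny, nzh)
    dz <- c(g$dz, rev(g$dz))
    zc <- cumsum(dz) - dz / 2
    flux_scale <- 2
  } else {
    dm <- c(nx, ny, nzh)
    u <- array(sol$u, dm); v <- array(sol$v, dm)
    w <- array(sol$w, dm); p <- array(sol$p, dm)
    mask <- array(sol$mask, dm)
    dz <- g$dz
    zc <- g$zc
    flux_scale <- 1
  }
  Re_true <- U * D / fluid$kinematic_viscosity
  Re_nominal <- U * D / fluid$nominal_kinematic_viscosity
  flux <- sol$flux_faces * flux_scale * U * D^2     # cm^3 s^-1
  yfaces <- c(0, cumsum(g$dy)) * D
  conv <- list(
    converged = sol$converged,
    plateaued = isTRUE(sol$plateaued),
    iterations = sol$iterations,
    residual = sol$residual, residual_history = sol$residual_history,
    max_divergence = sol$max_divergence,
    flux_faces = flux, y_faces = yfaces,
    flux_inlet = flux[1],
    flux_spread = diff(range(flux)) / abs(flux[1]),
    sim_time = if (mode == "unsteady") sol$sim_time * D / U else NA_real_,
    dt = if (mode == "unsteady") sol$dt_global * D / U else NA_real_
  )
  structure(list(
    x = g$xc * D, y = g$yc * D, z = zc * D,
    dx = g$dx * D, dy = g$dy * D, dz = dz * D,
    u = u * U, v = v * U, w = w * U,
    p = p * fluid$density * U^2,
    mask = mask,
    U = U, fluid = fluid, cell = cell, obstacles = obstacles,
    Re = Re_true, Re_nominal = Re_nominal,
    mode = mode, settings = settings,
    convergence = conv, tiles = 1L
  ), class = "flow_field")
}

check_convergence <- function(sol, settings, U) {
  if (!sol$converged && settings$mode == "steady") {
    if (is.na(sol$residual) || sol$residual > 0.03) {
      cond <- structure(
        class = c("gorgflow_convergence_error", "error", "condition"),
        list(message = sprintf(
          "steady solve did not converge: residual %.3g after %d iterations",
          sol$residual, sol$iterations),
          call = NULL, residual_history = sol$residual_history))
      stop(cond)
    }
    warning(sprintf(
      "steady residual plateaued at %.2g (tolerance %.2g); returning the pseudo-time-averaged field",
      sol$residual, settings$tol), call. = FALSE)
  }
  invisible(TRUE)
}

#' Steady laminar flow through a periodic cylinder-array cell
#'
#' Solves steady incompressible laminar flow in a unit cell with uniform
#' inflow, zero-pressure outflow, periodic side faces and free-slip
#' (symmetry) top/bottom faces, with no-slip on the stair-step rasterized
#' obstacles. The solver works in diameter/inlet-speed units internally,
#' so geometrically similar cells at different absolute scales reduce to
#' the same computation at equal Reynolds number.
#'
#' @param cell a [branch_cell()], [tentacle_cell()] or [pinnule_cell()].
#' @param U inlet (free-stream) speed in cm s^-1.
#' @param obstacles an [cell_obstacles()] set; defaults to the plain
#'   cylinder of `cell`.
#' @param fluid a [fluid_properties()] object.
#' @param settings a [solver_settings()] object.
#' @return A `flow_field`: cell-centered velocities (cm s^-1) and pressure
#'   (dyn cm^-2) on the graded grid, the solid mask, and a convergence
#'   report (residual history, per-cross-section volumetric flux).
#' @examples
#' \donttest{
#' fld <- solve_steady(branch_cell(2), U = 0.2)
#' leakiness_line(fld)
#' }
#' @export
solve_steady <- function(cell, U, obstacles = NULL,
                         fluid = fluid_properties(),
                         settings = solver_settings()) {
  stopifnot(inherits(cell, "cylinder_cell"), U > 0)
  if (is.null(obstacles)) obstacles <- cell_obstacles(cell)
  settings$mode <- "steady"
  run_solver(cell, U, obstacles, fluid, settings)
}

#' Time-marched flow solve
#'
#' Marches the time-dependent equations (artificial-compressibility form
#' with a global stable time step) over `total_time` seconds and returns
#' the final frame. With steady inflow the solution relaxes to the same
#' steady state as [solve_steady()]; the convergence report carries the
#' final steadiness measure so the agreement can be quantified.
#'
#' @inheritParams solve_steady
#' @param total_time simulated physical time in seconds; default 5 domain
#'   flow-through times (`5 * domain_length / U`).
#' @return A `flow_field` for the final frame (see [solve_steady()]).
#' @export
solve_unsteady <- function(cell, U, obstacles = NULL,
                           fluid = fluid_properties(),
                           settings = solver_settings(),
                           total_time = NULL) {
  stopifnot(inherits(cell, "cylinder_cell"))
  if (U < 0) stop("`U` must be non-negative", call. = FALSE)
  if (is.null(obstacles)) obstacles <- cell_obstacles(cell)
  settings$mode <- "unsteady"
  if (U == 0) {
    # no forcing: the flow stays identically at rest
    settings$mode <- "steady"
    fld <- run_solver(cell, 1, obstacles, fluid,
                      modifyList(settings, list(max_iter = 1L)), zero = TRUE)
    fld$U <- 0
    fld$mode <- "unsteady"
    return(fld)
  }
  if (is.null(total_time)) total_time <- 5 * cell$domain_length / U
  settings$total_time <- total_time
  run_solver(cell, U, obstacles, fluid, settings)
}

run_solver <- function(cell, U, obstacles, fluid, settings, zero = FALSE) {
  D <- cell$diameter
  Re_true <- U * D / fluid$kinematic_viscosity
  Re_nominal <- U * D / fluid$nominal_kinematic_viscosity
  if (Re_nominal > 200) {
    warning(sprintf(
      "nominal Re = %.3g exceeds ~200; flow past the array may be unsteady in reality, the steady solution is a model idealization",
      Re_nominal), call. = FALSE)
  }
  g <- cell_grid(cell, obstacles, settings)
  mode_i <- if (settings$mode == "unsteady") 1L else 0L
  tt <- if (mode_i == 1L) settings$total_time * U / D else 0
  init <- list(u = numeric(0), v = numeric(0), w = numeric(0), p = numeric(0))
  if (settings$cascade && mode_i == 0L && !zero &&
      settings$resolution >= 8) {
    coarse <- settings
    coarse$resolution <- max(4, settings$resolution / 2)
    coarse$cascade <- FALSE
    coarse$tol <- max(settings$tol * 10, 1e-3)
    coarse$max_iter <- min(settings$max_iter, 20000L)
    cf <- tryCatch(
      suppressWarnings(run_solver(cell, U, obstacles, fluid, coarse)),
      error = function(e) NULL)
    if (!is.null(cf)) {
      pts <- cbind(rep(g$xc, times = length(g$yc) * length(g$zc)),
                   rep(rep(g$yc, each = g$nx), times = length(g$zc)),
                   rep(g$zc, each = g$nx * length(g$yc))) * D
      vel <- gf_interp(cf$x, cf$y, cf$z, cf$u, cf$v, cf$w,
                       cell$cell_width, pts) / U
      pr <- gf_interp(cf$x, cf$y, cf$z, cf$p, cf$p, cf$p,
                      cell$cell_width, pts)[, 1] / (fluid$density * U^2)
      init <- list(u = vel[, 1], v = vel[, 2], w = vel[, 3], p = pr)
    }
  }
  # creeping-flow regimes are solved in viscous scaling: unit viscosity
  # with the advective term scaled by Re (identical steady state, far
  # better pseudo-time conditioning); pressure is rescaled on return
  visc_scaled <- Re_true < 1
  nu_arg <- if (visc_scaled) 1 else 1 / Re_true
  adv_arg <- if (visc_scaled) Re_true else 1
  p_scale <- if (visc_scaled) Re_true else 1
  solve_once <- function(cfl) {
    gf_solve(g$nx, length(g$dy), length(g$dz), g$dx, g$dy, g$dz,
             g$mask, nu_arg,
             settings$tol, settings$max_iter, cfl,
             mode_i, tt, settings$check_every, settings$verbose,
             init$u, init$v, init$w, init$p * p_scale,
             settings$pdiss %||% 1.0, settings$beta_k %||% 2.0, adv_arg,
             settings$stall_factor %||% 0.90)
  }
  sol <- solve_once(settings$cfl)
  if (mode_i == 0L && !sol$converged && is.na(sol$residual)) {
    # diverged pseudo-time iteration: retry once at a safer CFL
    sol <- solve_once(0.65 * settings$cfl)
  }
  sol$p <- sol$p / p_scale
  if (zero) {
    for (nm in c("u", "v", "w", "p")) sol[[nm]][] <- 0
    sol$flux_faces[] <- 0
    sol$converged <- TRUE
  } else {
    check_convergence(sol, settings, U)
  }
  fld <- finish_field(sol, g, cell, obstacles, U, fluid, settings, settings$mode)
  if (!zero && fld$convergence$max_divergence > settings$divergence_tol) {
    warning(sprintf("max relative divergence %.2g exceeds %.2g",
                    fld$convergence$max_divergence, settings$divergence_tol),
            call. = FALSE)
  }
  fld
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field: %s cell, G/D = %g, U = %g cm/s (Re = %.3g, nominal %.3g)\n",
              x$cell$scale_level, x$cell$g_over_d, x$U, x$Re, x$Re_nominal))
  cat(sprintf("  grid %d x %d x %d, %s solve: %s (residual %.2g, %d iterations)\n",
              length(x$x), length(x$y), length(x$z), x$mode,
              if (isTRUE(x$convergence$converged)) "converged" else "NOT converged",
              x$convergence$residual, x$convergence$iterations))
  if (x$tiles > 1L) cat(sprintf("  tiled x%d to width %g cm\n",
                                x$tiles, x$tiles * x$cell$cell_width))
  invisible(x)
}

#' @export
summary.flow_field <- function(object, ...) {
  fl <- object$convergence$flux_faces
  cat(sprintf("Mass conservation: inlet flux %.6g cm^3/s, spread across sections %.2g%%\n",
              object$convergence$flux_inlet, 100 * object$convergence$flux_spread))
  cat(sprintf("Max |div u| D/U in fluid cells: %.2g\n",
              object$convergence$max_divergence))
  cat(sprintf("Speed range: %.4g .. %.4g cm/s\n",
              0, max(sqrt(object$u^2 + object$v^2 + object$w^2))))
  invisible(object)
}

#' @param x a `flow_field`.
#' @param z height of the x-y slice to draw, cm; defaults to mid-height.
#' @param ... passed to [graphics::image()].
#' @rdname solve_steady
#' @export
plot.flow_field <- function(x, z = NULL, ...) {
  if (is.null(z)) z <- mean(range(x$z))
  k <- which.min(abs(x$z - z))
  sp <- sqrt(x$u[, , k]^2 + x$v[, , k]^2 + x$w[, , k]^2)
  image(x$x, x$y, sp, col = hcl.colors(64, "viridis"),
        xlab = "x (cm)", ylab = "y (cm)",
        main = sprintf("speed at z = %.3g cm (cm/s)", x$z[k]), ...)
  if (any(x$mask[, , k] == 1)) {
    contour(x$x, x$y, x$mask[, , k], levels = 0.5, add = TRUE,
            drawlabels = FALSE, col = "magenta", lwd = 2)
  }
  invisible(x)
}

#' Interpolate velocity at arbitrary points
#'
#' Trilinear interpolation of the cell-centered velocity samples; exact at
#' grid nodes and exact for fields linear in the coordinates. x is treated
#' periodically (the field tiles across gaps); y and z must lie inside the
#' domain. Points inside an obstacle return zero velocity.
#'
#' @param field a `flow_field`.
#' @param points length-3 vector or n x 3 matrix of (x, y, z) in cm.
#' @return An n x 3 matrix of velocity components (cm s^-1).
#' @export
interpolate_velocity <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  stopifnot(ncol(points) == 3)
  Ly <- field$cell$domain_length
  Lz <- field$cell$domain_height
  eps <- 1e-9
  bad <- points[, 2] < -eps | points[, 2] > Ly + eps |
    points[, 3] < -eps | points[, 3] > Lz + eps
  if (any(bad)) {
    stop(sprintf("%d point(s) outside the domain in a non-periodic direction",
                 sum(bad)), call. = FALSE)
  }
  out <- gf_interp(field$x, field$y, field$z,
                   field$u, field$v, field$w,
                   field$cell$cell_width, points)
  if (!is.null(field$obstacles) && length(field$obstacles$solids)) {
    ins <- locate(points, field$obstacles)$inside
    out[ins, ] <- 0
  }
  colnames(out) <- c("u", "v", "w")
  out
}
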