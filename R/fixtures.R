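# Analytic velocity fields and synthetic morphometric tables. These exist so
# every metric, interpolator and transport routine can be exercised against
# closed forms without running the flow solver.

#' Analytic flow-field fixtures
#'
#' Discretizes a closed-form, divergence-free velocity field onto a grid and
#' wraps it as a `flow_field`, so the leakiness metrics, the interpolator
#' and the agent transport can be checked against exact values.
#'
#' Kinds:
#' \describe{
#'   \item{uniform}{`u = (0, U, 0)` everywhere.}
#'   \item{linear_shear}{`v = U + shear * z`, a linear profile (trilinear
#'     interpolation reproduces it exactly).}
#'   \item{plane_channel}{parabolic profile across the cell width,
#'     `v = u0 (1 - (2x/w - 1)^2)`; its line average across the full width
#'     is `2/3 u0`.}
#'   \item{extruded_potential_cylinder}{2-d potential flow past a circular
#'     cross-section of radius `R` centered on the cell cylinder, extruded
#'     along z; zero normal velocity on the cross-section, zero velocity
#'     inside it.}
#' }
#'
#' @param kind one of the four fixture kinds.
#' @param cell a `cylinder_cell` providing the domain box (and obstacle for
#'   the potential kind).
#' @param U free-stream scale, cm s^-1.
#' @param parameters kind-specific parameters: `shear` (s^-1) for
#'   linear_shear, `u0` for plane_channel, `R` (cm) for the potential kind
#'   (defaults to the cell cylinder radius).
#' @param n grid sizes `c(nx, ny, nz)`.
#' @return A `flow_field` whose nodal values equal the closed form exactly;
#'   the closed form itself is attached as attribute `"evaluate"`
#'   (a `function(points)` returning an n x 3 velocity matrix).
#' @examples
#' fld <- analytic_field("uniform", branch_cell(2), U = 1)
#' leakiness_gap_flux(fld)$Le  # exactly 1
#' @export
analytic_field <- function(kind = c("uniform", "linear_shear", "plane_channel",
                                    "extruded_potential_cylinder"),
                           cell, U = 1, parameters = list(),
                           n = c(16, 48, 24)) {
  kind <- match.arg(kind)
  stopifnot(inherits(cell, "cylinder_cell"))
  w <- cell$cell_width
  evaluate <- switch(kind,
    uniform = function(p) cbind(0, rep(U, nrow(p)), 0),
    linear_shear = {
      shear <- parameters$shear %||% 0.5
      function(p) cbind(0, U + shear * p[, 3], 0)
    },
    plane_channel = {
      u0 <- parameters$u0 %||% U
      function(p) {
        xi <- 2 * ((p[, 1] %% w) / w) - 1
        cbind(0, u0 * (1 - xi^2), 0)
      }
    },
    extruded_potential_cylinder = {
      R <- parameters$R %||% (cell$diameter / 2)
      cx <- cell$center_x; cy <- cell$center_y
      function(p) {
        X <- (p[, 1] %% w) - cx
        Y <- p[, 2] - cy
        r2 <- X^2 + Y^2
        inside <- r2 < R^2
        r2[inside] <- R^2  # placeholder, zeroed below
        u <- -U * R^2 * 2 * X * Y / r2^2
        v <- U * (1 - R^2 * (Y^2 - X^2) / r2^2)
        u[inside] <- 0; v[inside] <- 0
        cbind(u, v, 0)
      }
    })
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  dx <- w / nx
  dy <- rep(cell$domain_length / ny, ny)
  dz <- rep(cell$domain_height / nz, nz)
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- cumsum(dy) - dy / 2
  zc <- cumsum(dz) - dz / 2
  pts <- cbind(rep(xc, times = ny * nz),
               rep(rep(yc, each = nx), times = nz),
               rep(zc, each = nx * ny))
  vel <- evaluate(pts)
  dm <- c(nx, ny, nz)
  obstacles <- if (kind == "extruded_potential_cylinder") {
    cell_obstacles(cell)
  } else NULL
  fld <- structure(list(
    x = xc, y = yc, z = zc, dx = dx, dy = dy, dz = dz,
    u = array(vel[, 1], dm), v = array(vel[, 2], dm), w = array(vel[, 3], dm),
    p = array(0, dm), mask = array(0L, dm),
    U = U, fluid = fluid_properties(), cell = cell, obstacles = obstacles,
    Re = NA_real_, Re_nominal = NA_real_, mode = "analytic",
    settings = NULL,
    convergence = list(converged = TRUE, iterations = 0L, residual = 0,
                       residual_history = numeric(0), max_divergence = 0,
                       flux_faces = numeric(0), y_faces = numeric(0),
                       flux_inlet = NA_real_, flux_spread = NA_real_,
                       sim_time = NA_real_, dt = NA_real_),
    tiles = 1L
  ), class = "flow_field")
  attr(fld, "evaluate") <- evaluate
  attr(fld, "kind") <- kind
  fld
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# printed morphometric ranges per structural level (ratio min/max)
morph_ranges <- list(
  branch = list(gd = c(1.3, 4), hd = c(4.5, 30), diameter = c(0.05, 0.3),
                unit = "cm"),
  tentacle = list(gd = c(1.75, 3), hd = NULL, diameter = c(20, 60),
                  unit = "px"),
  pinnule = list(gd = c(1.25, 2.5), hd = NULL, diameter = c(4, 12),
                 unit = "px")
)

#' Synthetic morphometric measurement tables
#'
#' Generates gap/diameter(/height) measurement records mimicking the
#' published per-specimen ranges at each level (branch G/D 1.3-4 with H/D
#' 4.5-30; tentacle G/D 1.75-3; pinnule G/D 1.25-2.5). Ratios are drawn
#' uniformly over the level's range -- the published tables give ranges, not
#' distributions, so this is a synthetic stand-in for testing the summary
#' statistics, not an inference about real colonies. Branch records carry cm
#' units; tentacle/pinnule records are in pixels (uncalibrated images).
#'
#' @param n_specimens number of synthetic specimens.
#' @param level `"branch"`, `"tentacle"` or `"pinnule"`.
#' @param seed integer seed; the same seed reproduces the table bit-exactly.
#' @param n_measurements measurements per specimen.
#' @return Data frame with columns `specimen`, `structure`, `measurement`,
#'   `diameter`, `gap`, `height` (branch only), `unit`.
#' @export
morphometric_table <- function(n_specimens, level = c("branch", "tentacle",
                                                      "pinnule"),
                               seed = 1L, n_measurements = 5L) {
  level <- match.arg(level)
  stopifnot(n_specimens >= 1)
  rng <- morph_ranges[[level]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(n_specimens), function(s) {
    d <- runif(n_measurements, rng$diameter[1], rng$diameter[2])
    gd <- runif(n_measurements, rng$gd[1], rng$gd[2])
    df <- data.frame(
      specimen = sprintf("synthetic-%s-%02d", level, s),
      structure = level,
      measurement = seq_len(n_measurements),
      diameter = d, gap = d * gd, unit = rng$unit)
    if (!is.null(rng$hd)) {
      df$height <- d * runif(n_measurements, rng$hd[1], rng$hd[2])
    }
    df
  })
  do.call(rbind, rows)
}
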