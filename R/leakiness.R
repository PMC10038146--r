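new_leakiness <- function(Le, metric, U, Q = NA_real_, A = NA_real_,
                          location = list()) {
  structure(list(Le = Le, metric = metric, Q = Q, A = A, U = U,
                 location = location), class = "leakiness")
}

#' @export
print.leakiness <- function(x, ...) {
  cat(sprintf("Leakiness (%s metric): Le = %.4g", x$metric, x$Le))
  if (x$metric == "gap_flux") {
    cat(sprintf("  [Q = %.4g cm^3/s, A = %.4g cm^2, U = %.4g cm/s]",
                x$Q, x$A, x$U))
  }
  cat("\n")
  invisible(x)
}

#' Gap-flux leakiness Q / (U A)
#'
#' Integrates the streamwise velocity over the gap window -- the rectangle
#' between neighbouring cylinder surfaces (width G) spanning the cylinder
#' height (H) -- in the cross-flow plane at the cylinder's streamwise
#' position, and divides by the flux an undisturbed free stream would carry
#' through the same area. Values above 1 indicate flow accelerating through
#' the gap; a zero field gives exactly 0 and a uniform field exactly 1.
#'
#' @param field a `flow_field` from [solve_steady()], [solve_unsteady()] or
#'   [analytic_field()].
#' @param y_offset streamwise offset of the sampling plane from the cylinder
#'   center, cm (for sensitivity checks).
#' @param n quadrature points per direction (midpoint rule).
#' @return A `leakiness` measurement object.
#' @export
leakiness_gap_flux <- function(field, y_offset = 0, n = 96) {
  cl <- field$cell
  U <- field$U
  if (U == 0) return(new_leakiness(0, "gap_flux", 0, Q = 0,
                                   A = cl$gap * cl$height))
  yplane <- cl$center_y + y_offset
  x0 <- cl$center_x + cl$diameter / 2
  xs <- x0 + (seq_len(n) - 0.5) / n * cl$gap
  zs <- cl$z0 + (seq_len(n) - 0.5) / n * cl$height
  pts <- cbind(rep(xs, times = n), yplane, rep(zs, each = n))
  if (!is.null(field$obstacles) && length(field$obstacles$solids)) {
    if (any(locate(pts, field$obstacles)$inside)) {
      stop("gap-flux sampling window intersects an obstacle", call. = FALSE)
    }
  }
  v <- gf_interp(field$x, field$y, field$z, field$u, field$v, field$w,
                 cl$cell_width, pts)[, 2]
  A <- cl$gap * cl$height
  Q <- mean(v) * A
  new_leakiness(Q / (U * A), "gap_flux", U, Q = Q, A = A,
                location = list(y = yplane))
}

#' Line-average leakiness
#'
#' Averages the streamwise velocity along a line normal to the flow -- by
#' default from the cylinder axis to the edge of the periodic cell at the
#' cylinder's mid-height -- and divides by the free-stream speed. Sample
#' points falling inside a solid contribute zero velocity and remain in the
#' averaging length (`from = "axis"`); `from = "surface"` instead starts the
#' line on the cylinder surface so only fluid is sampled.
#'
#' @param field a `flow_field`.
#' @param z line height in cm; defaults to the cylinder mid-height.
#' @param from `"axis"` (default) or `"surface"`.
#' @param line optional explicit line as `list(from = c(x, y, z),
#'   to = c(x, y, z))`, overriding `z` and `from`.
#' @param n number of sample points.
#' @return A `leakiness` measurement object.
#' @export
leakiness_line <- function(field, z = NULL, from = c("axis", "surface"),
                           line = NULL, n = 256) {
  cl <- field$cell
  U <- field$U
  from <- match.arg(from)
  if (is.null(line)) {
    if (is.null(z)) z <- (cl$z0 + cl$z1) / 2
    x0 <- if (from == "axis") cl$center_x else cl$center_x + cl$diameter / 2
    line <- list(from = c(x0, cl$center_y, z),
                 to = c(cl$center_x + cl$cell_width / 2, cl$center_y, z))
  }
  if (U == 0) return(new_leakiness(0, "line_average", 0, location = line))
  ts <- (seq_len(n) - 0.5) / n
  pts <- cbind(line$from[1] + ts * (line$to[1] - line$from[1]),
               line$from[2] + ts * (line$to[2] - line$from[2]),
               line$from[3] + ts * (line$to[3] - line$from[3]))
  v <- gf_interp(field$x, field$y, field$z, field$u, field$v, field$w,
                 cl$cell_width, pts)[, 2]
  if (!is.null(field$obstacles) && length(field$obstacles$solids)) {
    ins <- locate(pts, field$obstacles)$inside
    if (all(ins)) stop("sampling line lies entirely inside a solid",
                       call. = FALSE)
    v[ins] <- 0
  }
  new_leakiness(mean(v) / U, "line_average", U,
                location = c(line, list(from_mode = from)))
}

#' Leakiness sweep over gap ratio and flow speed
#'
#' Solves the steady unit-cell flow for every combination of `g_over_d` and
#' inlet speed and records both leakiness metrics. Speeds can be given
#' directly (`U`, cm/s) or as nominal Reynolds numbers (`Re`, converted
#' through the rounded kinematic viscosity in `fluid`). Solver failures are
#' logged per record and do not abort the sweep.
#'
#' @param scale_level `"branch"`, `"tentacle"` or `"pinnule"`.
#' @param g_over_d vector of gap-to-diameter ratios.
#' @param U vector of inlet speeds (cm/s); alternative to `Re`.
#' @param Re vector of nominal Reynolds numbers; alternative to `U`.
#' @param fluid a [fluid_properties()].
#' @param settings a [solver_settings()].
#' @param quiet suppress per-record progress messages.
#' @return A data frame of class `leakiness_sweep`: one row per
#'   (G/D, U) with nominal and true Re, both leakiness metrics and the
#'   convergence status.
#' @export
leakiness_sweep <- function(scale_level = c("branch", "tentacle", "pinnule"),
                            g_over_d, U = NULL, Re = NULL,
                            fluid = fluid_properties(),
                            settings = solver_settings(),
                            quiet = TRUE) {
  scale_level <- match.arg(scale_level)
  make_cell <- switch(scale_level, branch = branch_cell,
                      tentacle = tentacle_cell, pinnule = pinnule_cell)
  D <- make_cell(max(g_over_d))$diameter
  if (is.null(U)) {
    if (is.null(Re)) stop("give either `U` or nominal `Re`", call. = FALSE)
    U <- Re * fluid$nominal_kinematic_viscosity / D
  }
  grid <- expand.grid(g_over_d = g_over_d, U = U, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid$g_over_d[r]; u <- grid$U[r]
    rec <- data.frame(scale_level = scale_level, g_over_d = g, U = u,
                      Re_nominal = u * D / fluid$nominal_kinematic_viscosity,
                      Re_true = u * D / fluid$kinematic_viscosity,
                      Le_gap = NA_real_, Le_line = NA_real_,
                      converged = FALSE, residual = NA_real_,
                      iterations = NA_integer_, error = NA_character_)
    if (!quiet) message(sprintf("solving %s G/D=%g U=%g", scale_level, g, u))
    fld <- tryCatch(
      withCallingHandlers(
        solve_steady(make_cell(g), u, fluid = fluid, settings = settings),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fld, "error")) {
      rec$error <- conditionMessage(fld)
      return(rec)
    }
    rec$Le_gap <- leakiness_gap_flux(fld)$Le
    rec$Le_line <- leakiness_line(fld)$Le
    rec$converged <- fld$convergence$converged
    rec$residual <- fld$convergence$residual
    rec$iterations <- fld$convergence$iterations
    rec
  })
  out <- do.call(rbind, rows)
  class(out) <- c("leakiness_sweep", "data.frame")
  out
}

#' @param x a `leakiness_sweep`.
#' @param metric which leakiness column to draw.
#' @param ... ignored.
#' @rdname leakiness_sweep
#' @export
plot.leakiness_sweep <- function(x, metric = c("Le_gap", "Le_line"), ...) {
  metric <- match.arg(metric)
  gs <- sort(unique(x$g_over_d))
  cols <- hcl.colors(max(length(gs), 2), "Dark 2")
  plot(NULL, xlim = range(x$Re_nominal), ylim = range(0, x[[metric]], 1,
                                                      na.rm = TRUE),
       log = "x", xlab = "nominal Re", ylab = "leakiness Le",
       main = sprintf("%s level (%s)", x$scale_level[1], metric))
  for (i in seq_along(gs)) {
    s <- x[x$g_over_d == gs[i], ]
    s <- s[order(s$Re_nominal), ]
    lines(s$Re_nominal, s[[metric]], col = cols[i], type = "b", pch = 16)
  }
  legend("bottomright", legend = sprintf("G/D = %g", gs), col = cols,
         lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Streamwise drag force on the obstacles of a cell solution
#'
#' Control-volume momentum balance between the inlet and outlet planes:
#' with periodic sides and free-slip top/bottom, the streamwise force on
#' the obstacle set equals the loss of momentum flux plus the pressure
#' force difference between the two planes.
#'
#' @param field a converged `flow_field`.
#' @return List with `force` (dyn), `force_per_span` (dyn cm^-1, per unit
#'   cylinder length) and the plane integrals used.
#' @export
drag_force <- function(field) {
  rho <- field$fluid$density
  dA <- outer(rep(field$dx, length(field$x)), field$dz)
  plane <- function(j) {
    mom <- sum((rho * field$v[, j, ]^2 + field$p[, j, ]) * dA)
    mom
  }
  f <- plane(1) - plane(length(field$y))
  list(force = f, force_per_span = f / field$cell$height,
       inlet = plane(1), outlet = plane(length(field$y)))
}
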