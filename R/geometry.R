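#' Seawater-like fluid properties
#'
#' Container for the fluid constants used by the flow solver and the
#' dimensionless-number calculators. Defaults correspond to seawater at
#' roughly 20 degrees C: density 1.025 g cm^-3 and dynamic viscosity
#' 0.0108 poise. The kinematic viscosity is derived as mu/rho; a separate
#' rounded "nominal" kinematic viscosity (0.01 cm^2 s^-1) is carried along
#' because integer Reynolds-number labels such as Re = 2 at U = 0.2 cm s^-1
#' for a 0.1 cm cylinder follow that rounding, while simulations use the
#' true viscosity.
#'
#' @param density fluid density in g cm^-3.
#' @param dynamic_viscosity dynamic viscosity in poise (g cm^-1 s^-1).
#' @param nominal_kinematic_viscosity rounded kinematic viscosity in
#'   cm^2 s^-1 used for Reynolds-number labelling.
#' @return An object of class `fluid_properties`.
#' @examples
#' fl <- fluid_properties()
#' fl$kinematic_viscosity  # mu / rho
#' @export
fluid_properties <- function(density = 1.025,
                             dynamic_viscosity = 0.0108,
                             nominal_kinematic_viscosity = 0.01) {
  stopifnot(density > 0, dynamic_viscosity > 0,
            nominal_kinematic_viscosity > 0)
  structure(list(
    density = density,
    dynamic_viscosity = dynamic_viscosity,
    kinematic_viscosity = dynamic_viscosity / density,
    nominal_kinematic_viscosity = nominal_kinematic_viscosity
  ), class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties (CGS units)\n")
  cat(sprintf("  density:             %g g cm^-3\n", x$density))
  cat(sprintf("  dynamic viscosity:   %g P\n", x$dynamic_viscosity))
  cat(sprintf("  kinematic viscosity: %g cm^2 s^-1 (nominal %g)\n",
              x$kinematic_viscosity, x$nominal_kinematic_viscosity))
  invisible(x)
}

# Internal constructor shared by the three scale-level helpers.
# All lengths are stored in cm. Coordinates: x periodic (across gaps),
# y streamwise, z along the cylinder axis. The cylinder is centered across
# the cell width and centered vertically in the domain.
new_cylinder_cell <- function(scale_level, diameter, height, g_over_d,
                              domain_length, domain_height, inlet_offset) {
  if (!is.numeric(g_over_d) || length(g_over_d) != 1L || !is.finite(g_over_d) ||
      g_over_d <= 0) {
    stop("`g_over_d` must be a single positive number", call. = FALSE)
  }
  gap <- g_over_d * diameter
  cell_width <- diameter + gap
  stopifnot(cell_width < domain_length, height < domain_height)
  structure(list(
    scale_level = scale_level,
    diameter = diameter,
    height = height,
    gap = gap,
    g_over_d = g_over_d,
    cell_width = cell_width,
    domain_length = domain_length,
    domain_height = domain_height,
    inlet_offset = inlet_offset,
    # cylinder placement (cm)
    center_x = cell_width / 2,
    center_y = inlet_offset,
    z0 = (domain_height - height) / 2,
    z1 = (domain_height + height) / 2,
    boundary_roles = list(
      x_low = "periodic", x_high = "periodic",
      y_low = "inlet", y_high = "outlet",
      z_low = "symmetry", z_high = "symmetry"
    )
  ), class = "cylinder_cell")
}

#' Periodic unit cells for the three structural levels
#'
#' Construct the periodic unit-cell domain for an infinite array of
#' finite-height cylinders at the branch, tentacle or pinnule scale.
#' A single cylinder sits in a box that is periodic across the gaps (x),
#' has a uniform-inflow inlet and zero-pressure outlet along the stream
#' (y), and free-slip symmetry planes at top and bottom (z). The cell
#' width is `D * (1 + g_over_d)` so that the surface-to-surface gap
#' between periodic images is `g_over_d * D`.
#'
#' The three levels are geometrically similar (height/diameter = 10,
#' domain 100 D long and 40 D high, cylinder 20 D downstream of the
#' inlet); they differ in absolute size:
#' \describe{
#'   \item{branch}{D = 0.1 cm, H = 1 cm, domain 10 x 4 cm, cylinder 2 cm
#'     from the inlet.}
#'   \item{tentacle}{D = 0.025 cm, H = 0.25 cm, domain 2.5 x 1.0 cm,
#'     cylinder 0.5 cm from the inlet.}
#'   \item{pinnule}{D = 0.025 mm, H = 0.25 mm, domain 2.5 x 1.0 mm,
#'     cylinder 0.5 mm from the inlet (stored in cm).}
#' }
#'
#' @param g_over_d gap-to-diameter ratio G/D. Branch cells accept
#'   (0, 10]; tentacle and pinnule cells accept [1, 5].
#' @return An object of class `cylinder_cell`.
#' @examples
#' branch_cell(2)$cell_width    # 0.3 cm
#' pinnule_cell(1.25)$cell_width # 0.05625 mm expressed in cm
#' @export
branch_cell <- function(g_over_d) {
  if (!is.numeric(g_over_d) || length(g_over_d) != 1L ||
      !is.finite(g_over_d) || g_over_d <= 0 || g_over_d > 10) {
    stop("branch-scale `g_over_d` must lie in (0, 10]", call. = FALSE)
  }
  new_cylinder_cell("branch", diameter = 0.1, height = 1, g_over_d = g_over_d,
                    domain_length = 10, domain_height = 4, inlet_offset = 2)
}

#' @rdname branch_cell
#' @export
tentacle_cell <- function(g_over_d) {
  if (!is.numeric(g_over_d) || length(g_over_d) != 1L ||
      !is.finite(g_over_d) || g_over_d < 1 || g_over_d > 5) {
    stop("tentacle-scale `g_over_d` must lie in [1, 5]", call. = FALSE)
  }
  new_cylinder_cell("tentacle", diameter = 0.025, height = 0.25,
                    g_over_d = g_over_d,
                    domain_length = 2.5, domain_height = 1, inlet_offset = 0.5)
}

#' @rdname branch_cell
#' @export
pinnule_cell <- function(g_over_d) {
  if (!is.numeric(g_over_d) || length(g_over_d) != 1L ||
      !is.finite(g_over_d) || g_over_d < 1 || g_over_d > 5) {
    stop("pinnule-scale `g_over_d` must lie in [1, 5]", call. = FALSE)
  }
  # native units are mm; stored in cm like everything else
  new_cylinder_cell("pinnule", diameter = 0.0025, height = 0.025,
                    g_over_d = g_over_d,
                    domain_length = 0.25, domain_height = 0.1,
                    inlet_offset = 0.05)
}

#' @export
print.cylinder_cell <- function(x, ...) {
  cat(sprintf("Periodic cylinder-array unit cell (%s scale)\n", x$scale_level))
  cat(sprintf("  D = %g cm, H = %g cm, G/D = %g (gap %g cm)\n",
              x$diameter, x$height, x$g_over_d, x$gap))
  cat(sprintf("  cell width %g cm, domain %g x %g cm, cylinder %g cm from inlet\n",
              x$cell_width, x$domain_length, x$domain_height, x$inlet_offset))
  invisible(x)
}

#' Idealized polyp geometry attached to a branch cylinder
#'
#' Parameters of the idealized feeding polyp used to decorate a branch
#' cylinder: a short stalk capped by eight straight solid tentacles splayed
#' around the oral axis. Four polyps sit on each of the two cylinder faces
#' normal to the incident flow. The defaults give each polyp a tentacle
#' length of 0.1 cm and an overall height (reach from the branch surface)
#' of about 0.09 cm. Stalk and tentacle diameters and the splay angle are
#' tunable model choices, not measured constants.
#'
#' @param polyps_per_side polyps on each of the upstream/downstream faces.
#' @param tentacles_per_polyp tentacles per polyp.
#' @param tentacle_length tentacle length in cm.
#' @param polyp_height reach of the polyp from the branch surface in cm.
#' @param tentacle_diameter,stalk_diameter obstacle diameters in cm.
#' @param splay_angle angle between each tentacle and the oral axis, degrees.
#' @return An object of class `polyp_model`.
#' @export
polyp_model <- function(polyps_per_side = 4,
                        tentacles_per_polyp = 8,
                        tentacle_length = 0.1,
                        polyp_height = 0.09,
                        tentacle_diameter = 0.0125,
                        stalk_diameter = 0.03,
                        splay_angle = 45) {
  stopifnot(polyps_per_side >= 0, tentacles_per_polyp >= 1,
            tentacle_length > 0, polyp_height > 0,
            tentacle_diameter > 0, stalk_diameter > 0,
            splay_angle > 0, splay_angle < 90)
  axial_reach <- tentacle_length * cospi(splay_angle / 180)
  if (axial_reach >= polyp_height) {
    stop("tentacle axial reach exceeds the requested polyp height; ",
         "reduce `tentacle_length` or increase `splay_angle`", call. = FALSE)
  }
  structure(list(
    polyps_per_side = as.integer(polyps_per_side),
    tentacles_per_polyp = as.integer(tentacles_per_polyp),
    tentacle_length = tentacle_length,
    polyp_height = polyp_height,
    tentacle_diameter = tentacle_diameter,
    stalk_diameter = stalk_diameter,
    splay_angle = splay_angle,
    stalk_length = polyp_height - axial_reach
  ), class = "polyp_model")
}

#' Obstacle set for a unit cell, optionally decorated with polyps
#'
#' Build the analytic solid set used for grid masking, agent capture and
#' distance queries: the central finite cylinder plus, optionally, the
#' idealized polyps of [polyp_model()]. Each polyp is one stalk capsule and
#' `tentacles_per_polyp` tentacle capsules splayed around an oral axis that
#' points up- or downstream. Polyp centers are evenly spaced along the
#' cylinder height at heights H/8, 3H/8, 5H/8 and 7H/8 from the cylinder
#' base (for the default four per side).
#'
#' @param cell a `cylinder_cell`.
#' @param polyps a `polyp_model`, or `NULL` for a plain cylinder.
#' @return An object of class `obstacle_set`: a list of solids (finite
#'   vertical cylinders and capsules) plus the periodic cell metadata.
#' @examples
#' obs <- cell_obstacles(branch_cell(2), polyp_model())
#' length(obs$solids)  # 1 + 8 * (1 + 8) = 73
#' @export
cell_obstacles <- function(cell, polyps = NULL) {
  stopifnot(inherits(cell, "cylinder_cell"))
  solids <- list(list(
    type = "cylinder",
    center = c(cell$center_x, cell$center_y),
    radius = cell$diameter / 2,
    z0 = cell$z0, z1 = cell$z1
  ))

  if (!is.null(polyps)) {
    stopifnot(inherits(polyps, "polyp_model"))
    if (cell$scale_level != "branch") {
      stop("polyp decoration is defined for branch-scale cells", call. = FALSE)
    }
    if (polyps$polyps_per_side > 0) {
      R <- cell$diameter / 2
      n <- polyps$polyps_per_side
      zs <- cell$z0 + cell$height * (seq_len(n) * 2 - 1) / (2 * n)
      splay <- polyps$splay_angle * pi / 180
      nt <- polyps$tentacles_per_polyp
      # azimuth offset keeps the tentacle fan symmetric under both x- and
      # z-reflection through the polyp axis
      phis <- (seq_len(nt) - 0.5) * 2 * pi / nt
      for (side in c(1, -1)) {
        for (zp in zs) {
          base <- c(cell$center_x, cell$center_y + side * (R - 0.2 * R), zp)
          tip <- base + c(0, side * (0.2 * R + polyps$stalk_length), 0)
          solids[[length(solids) + 1L]] <- list(
            type = "capsule", p0 = base, p1 = tip,
            radius = polyps$stalk_diameter / 2
          )
          for (phi in phis) {
            dir <- c(sin(splay) * cos(phi),
                     side * cos(splay),
                     sin(splay) * sin(phi))
            solids[[length(solids) + 1L]] <- list(
              type = "capsule", p0 = tip,
              p1 = tip + polyps$tentacle_length * dir,
              radius = polyps$tentacle_diameter / 2
            )
          }
        }
      }
      # periodic-image overlap check: solids must stay clear of the cell faces
      max_reach <- max(vapply(solids, function(s) {
        if (s$type == "cylinder") abs(s$center[1] - cell$center_x) + s$radius
        else max(abs(s$p0[1] - cell$center_x), abs(s$p1[1] - cell$center_x)) +
          s$radius
      }, numeric(1)))
      if (max_reach >= cell$cell_width / 2) {
        stop("polyp tentacles overlap the periodic images; ",
             "reduce tentacle length or splay", call. = FALSE)
      }
    }
  }

  structure(list(
    solids = solids,
    cell_width = cell$cell_width,
    cell = cell,
    has_polyps = !is.null(polyps) &&
      (if (is.null(polyps)) FALSE else polyps$polyps_per_side > 0),
    polyp_model = polyps
  ), class = "obstacle_set")
}

#' @export
print.obstacle_set <- function(x, ...) {
  cat(sprintf("Obstacle set: %d solid(s) in a %s-scale cell (G/D = %g)%s\n",
              length(x$solids), x$cell$scale_level, x$cell$g_over_d,
              if (x$has_polyps) ", polyp-decorated" else ""))
  invisible(x)
}

#' Locate points relative to an obstacle set
#'
#' Signed-distance query used by the solver's grid masking and the agent
#' capture detector. Points are wrapped into the periodic cell in x, and
#' the nearest of the periodic obstacle images is used, so the result is
#' invariant under x-translation by any multiple of the cell width.
#'
#' @param points numeric vector of length 3 or an n x 3 matrix of (x, y, z)
#'   coordinates in cm.
#' @param obstacles an `obstacle_set`.
#' @return A data frame with columns `inside` (logical; distance <= 0) and
#'   `distance` (signed distance in cm, negative inside the solid).
#' @examples
#' obs <- cell_obstacles(branch_cell(2))
#' cl <- obs$cell
#' locate(c(cl$center_x, cl$center_y, 2), obs)  # center: inside, -D/2
#' @export
locate <- function(points, obstacles) {
  stopifnot(inherits(obstacles, "obstacle_set"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  stopifnot(ncol(points) == 3)
  sm <- solids_matrices(obstacles)
  d <- gf_signed_distance(points, sm$cyl, sm$cap, obstacles$cell_width)
  data.frame(inside = d <= 0, distance = d)
}
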