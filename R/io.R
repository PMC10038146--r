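# Readers/writers: legacy-ASCII VTK rectilinear grids for fields (with a
# YAML sidecar for cell/fluid metadata), ASCII STL for obstacle surfaces,
# CSV for sweep and capture tables, YAML run configs.

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")

config_hash <- function(x) {
  # tiny FNV-1a-style mix over the deparsed object, kept in 31-bit range
  # for R's bitwXor; a provenance stamp, not cryptography
  s <- paste(deparse(x), collapse = "")
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

provenance <- function(seed = NA, config = NULL) {
  list(package = "gorgflow",
       version = as.character(utils::packageVersion("gorgflow")),
       seed = seed,
       config_hash = if (is.null(config)) NA_character_ else config_hash(config))
}

#' Write and read flow fields (legacy ASCII VTK rectilinear grid)
#'
#' `write_field()` stores the grid coordinates, velocity vectors, pressure
#' and solid mask as a legacy-ASCII VTK `RECTILINEAR_GRID` (full double
#' precision), plus a YAML sidecar `<path>.yaml` carrying the units, inlet
#' speed, fluid constants, cell geometry, convergence summary and a
#' provenance stamp (package version, seed, config hash). `read_field()`
#' restores a `flow_field` that round-trips within float representation.
#'
#' @param field a `flow_field`.
#' @param path output `.vtk` path.
#' @param seed seed to record in the provenance stamp.
#' @return `write_field` returns `path` invisibly; `read_field` a
#'   `flow_field`.
#' @export
write_field <- function(field, path, seed = NA) {
  nx <- length(field$x); ny <- length(field$y); nz <- length(field$z)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     sprintf("gorgflow flow field (units cm, cm/s); see %s.yaml", basename(path)),
     "ASCII", "DATASET RECTILINEAR_GRID",
     sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
     sprintf("X_COORDINATES %d double", nx), fmt_nums(field$x),
     sprintf("Y_COORDINATES %d double", ny), fmt_nums(field$y),
     sprintf("Z_COORDINATES %d double", nz), fmt_nums(field$z),
     sprintf("POINT_DATA %d", nx * ny * nz),
     "VECTORS velocity double")
  vel <- cbind(as.vector(field$u), as.vector(field$v), as.vector(field$w))
  writeLines(apply(vel, 1, fmt_nums), con)
  wl("SCALARS pressure double 1", "LOOKUP_TABLE default",
     sprintf("%.17g", as.vector(field$p)),
     "SCALARS mask int 1", "LOOKUP_TABLE default",
     sprintf("%d", as.integer(field$mask)))
  meta <- list(
    units = list(length = "cm", velocity = "cm s-1", pressure = "dyn cm-2"),
    U = field$U, tiles = field$tiles, mode = field$mode,
    Re = field$Re, Re_nominal = field$Re_nominal,
    cell = list(scale_level = field$cell$scale_level,
                g_over_d = field$cell$g_over_d),
    has_polyps = isTRUE(field$obstacles$has_polyps),
    fluid = field$fluid[c("density", "dynamic_viscosity",
                          "nominal_kinematic_viscosity")],
    convergence = field$convergence[c("converged", "iterations", "residual",
                                      "max_divergence")],
    provenance = provenance(seed, list(field$cell, field$U))
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @param path the `.vtk` path written by `write_field()`.
#' @rdname write_field
#' @export
read_field <- function(path) {
  ln <- readLines(path)
  need <- function(pat) {
    i <- grep(pat, ln)
    if (!length(i)) stop(sprintf("malformed field file '%s': missing '%s'",
                                 path, pat), call. = FALSE)
    i[1]
  }
  dims <- as.integer(strsplit(ln[need("^DIMENSIONS")], " ")[[1]][2:4])
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  getvec <- function(tag, n) {
    i <- need(tag)
    vals <- as.numeric(strsplit(trimws(ln[i + 1]), "\\s+")[[1]])
    if (length(vals) != n || anyNA(vals)) {
      stop(sprintf("malformed field file '%s' at line %d (%s)", path, i + 1, tag),
           call. = FALSE)
    }
    vals
  }
  x <- getvec("^X_COORDINATES", nx)
  y <- getvec("^Y_COORDINATES", ny)
  z <- getvec("^Z_COORDINATES", nz)
  npt <- nx * ny * nz
  iv <- need("^VECTORS velocity")
  if (iv + npt > length(ln)) stop(sprintf("truncated field file '%s'", path),
                                  call. = FALSE)
  vel <- t(vapply(strsplit(trimws(ln[iv + seq_len(npt)]), "\\s+"),
                  function(s) as.numeric(s), numeric(3)))
  if (anyNA(vel)) stop(sprintf("malformed velocity data in '%s'", path),
                       call. = FALSE)
  ip <- need("^SCALARS pressure") + 1L
  if (ip + npt > length(ln)) stop(sprintf("truncated field file '%s'", path),
                                  call. = FALSE)
  p <- as.numeric(ln[ip + seq_len(npt)])
  im <- need("^SCALARS mask") + 1L
  if (im + npt > length(ln)) stop(sprintf("truncated field file '%s'", path),
                                  call. = FALSE)
  msk <- as.integer(ln[im + seq_len(npt)])
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  cell <- NULL; obstacles <- NULL; fluid <- fluid_properties(); U <- 1
  tiles <- 1L
  if (!is.null(meta)) {
    maker <- switch(meta$cell$scale_level, branch = branch_cell,
                    tentacle = tentacle_cell, pinnule = pinnule_cell)
    cell <- maker(meta$cell$g_over_d)
    obstacles <- cell_obstacles(cell, if (isTRUE(meta$has_polyps)) polyp_model())
    fluid <- fluid_properties(meta$fluid$density, meta$fluid$dynamic_viscosity,
                              meta$fluid$nominal_kinematic_viscosity)
    U <- meta$U
    tiles <- as.integer(meta$tiles)
  }
  widths_from_centers <- function(cc) {
    f <- 0
    out <- numeric(length(cc))
    for (i in seq_along(cc)) {
      out[i] <- 2 * (cc[i] - f)
      f <- f + out[i]
    }
    out
  }
  dm <- c(nx, ny, nz)
  structure(list(
    x = x, y = y, z = z,
    dx = if (nx > 1) x[2] - x[1] else NA_real_,
    dy = widths_from_centers(y),
    dz = widths_from_centers(z),
    u = array(vel[, 1], dm), v = array(vel[, 2], dm), w = array(vel[, 3], dm),
    p = array(p, dm), mask = array(msk, dm),
    U = U, fluid = fluid, cell = cell, obstacles = obstacles,
    Re = meta$Re %||% NA_real_, Re_nominal = meta$Re_nominal %||% NA_real_,
    mode = meta$mode %||% "unknown", settings = NULL,
    convergence = c(meta$convergence %||% list(converged = NA),
                    list(residual_history = numeric(0),
                         flux_faces = numeric(0), y_faces = numeric(0),
                         flux_inlet = NA_real_, flux_spread = NA_real_,
                         max_divergence = meta$convergence$max_divergence %||% NA_real_,
                         sim_time = NA_real_, dt = NA_real_)),
    tiles = tiles
  ), class = "flow_field")
}

#' Export obstacle surfaces as ASCII STL
#'
#' Triangulates the cylinders and capsules of an obstacle set (for
#' visualization in standard mesh viewers).
#'
#' @param obstacles an `obstacle_set`.
#' @param path output `.stl` path.
#' @param n_theta azimuthal facets per solid.
#' @return `path`, invisibly.
#' @export
write_obstacles_stl <- function(obstacles, path, n_theta = 24) {
  tri <- list()
  add_tri <- function(a, b, c) tri[[length(tri) + 1L]] <<- rbind(a, b, c)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)
  for (s in obstacles$solids) {
    if (s$type == "cylinder") {
      cx <- s$center[1]; cy <- s$center[2]; r <- s$radius
      for (i in seq_len(n_theta)) {
        p1 <- c(cx + r * cos(th[i]), cy + r * sin(th[i]))
        p2 <- c(cx + r * cos(th[i + 1]), cy + r * sin(th[i + 1]))
        add_tri(c(p1, s$z0), c(p2, s$z0), c(p2, s$z1))
        add_tri(c(p1, s$z0), c(p2, s$z1), c(p1, s$z1))
        add_tri(c(cx, cy, s$z1), c(p1, s$z1), c(p2, s$z1))
        add_tri(c(cx, cy, s$z0), c(p2, s$z0), c(p1, s$z0))
      }
    } else {
      a <- s$p0; b <- s$p1; r <- s$radius
      ax <- b - a; ax <- ax / sqrt(sum(ax^2))
      ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
              ax[3] * e1[1] - ax[1] * e1[3],
              ax[1] * e1[2] - ax[2] * e1[1])
      ring <- function(center) {
        t(vapply(th[-length(th)],
                 function(t0) center + r * cos(t0) * e1 + r * sin(t0) * e2,
                 numeric(3)))
      }
      r0 <- ring(a); r1 <- ring(b)
      for (i in seq_len(n_theta)) {
        j <- if (i == n_theta) 1L else i + 1L
        add_tri(r0[i, ], r1[i, ], r1[j, ])
        add_tri(r0[i, ], r1[j, ], r0[j, ])
        add_tri(a, r0[j, ], r0[i, ])
        add_tri(b, r1[i, ], r1[j, ])
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid gorgflow_obstacles", con)
  for (t0 in tri) {
    n <- c(0, 0, 1)
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         t0[, 1], t0[, 2], t0[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid gorgflow_obstacles", con)
  invisible(path)
}

#' Run configuration
#'
#' A serializable description of a full pipeline run: which scale level,
#' which G/D and speed grids, solver and agent settings, output directory
#' and seed. A run is reproducible from its config alone.
#'
#' @param scale_level `"branch"`, `"tentacle"` or `"pinnule"`.
#' @param g_over_d gap-ratio grid.
#' @param U inlet-speed grid (cm/s); alternative to `Re`.
#' @param Re nominal Reynolds grid; alternative to `U`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param solver list of [solver_settings()] overrides.
#' @param agents `NULL` to skip the capture experiment, or a list of
#'   [agent_params()] overrides.
#' @param metrics leakiness metrics to record.
#' @param write_fields write each solved field as VTK.
#' @return A `run_config` object.
#' @export
run_config <- function(scale_level = "branch", g_over_d = 2, U = NULL,
                       Re = NULL, out_dir = tempfile("gorgflow-run-"),
                       seed = 1L, solver = list(), agents = NULL,
                       metrics = c("gap_flux", "line_average"),
                       write_fields = TRUE) {
  if (is.null(U) && is.null(Re)) stop("give either `U` or `Re`", call. = FALSE)
  bad <- setdiff(names(solver), names(formals(solver_settings)))
  if (length(bad)) stop("unknown solver settings: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(agents)) {
    bad <- setdiff(names(agents), names(formals(agent_params)))
    if (length(bad)) stop("unknown agent params: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(list(scale_level = scale_level, g_over_d = g_over_d, U = U,
                 Re = Re, out_dir = out_dir, seed = as.integer(seed),
                 solver = solver, agents = agents, metrics = metrics,
                 write_fields = isTRUE(write_fields)),
            class = "run_config")
}

#' @param path YAML file path.
#' @rdname run_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Execute a configured pipeline run
#'
#' Solves the configured sweep, writes leakiness tables (CSV with unit
#' header comments), optional VTK fields, the optional capture-experiment
#' tables, a resolved copy of the config and a plain-text log into the
#' output directory.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return The output directory, invisibly.
#' @export
run <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
  }
  logmsg("gorgflow %s run, seed %d, config hash %s",
         utils::packageVersion("gorgflow"), config$seed, config_hash(config))
  settings <- do.call(solver_settings, config$solver)
  sweep <- leakiness_sweep(config$scale_level, config$g_over_d,
                           U = config$U, Re = config$Re, settings = settings)
  csv <- file.path(config$out_dir, "leakiness.csv")
  writeLines(c("# gorgflow leakiness sweep",
               sprintf("# version %s, seed %d, config %s",
                       utils::packageVersion("gorgflow"), config$seed,
                       config_hash(config)),
               "# units: U cm/s; Le dimensionless"), csv)
  suppressWarnings(write.table(sweep, csv, append = TRUE, sep = ",",
                               row.names = FALSE, qmethod = "double"))
  logmsg("leakiness sweep: %d records", nrow(sweep))
  if (config$write_fields) {
    maker <- switch(config$scale_level, branch = branch_cell,
                    tentacle = tentacle_cell, pinnule = pinnule_cell)
    for (r in seq_len(nrow(sweep))) {
      if (!isTRUE(sweep$converged[r])) next
      fld <- suppressWarnings(
        solve_steady(maker(sweep$g_over_d[r]), sweep$U[r], settings = settings))
      write_field(fld, file.path(config$out_dir,
                                 sprintf("field_g%g_U%g.vtk",
                                         sweep$g_over_d[r], sweep$U[r])),
                  seed = config$seed)
    }
  }
  if (!is.null(config$agents)) {
    params <- do.call(agent_params, modifyList(config$agents,
                                               list(seed = config$seed)))
    cap <- run_capture_experiment(config$g_over_d,
                                  Re = config$Re %||%
                                    (config$U * 10),
                                  params = params, settings = settings)
    write.csv(cap$summary, file.path(config$out_dir, "capture_summary.csv"),
              row.names = FALSE)
    write.csv(cap$replicates, file.path(config$out_dir, "capture_replicates.csv"),
              row.names = FALSE)
    logmsg("capture experiment: %d combinations", nrow(cap$summary))
  }
  write_config(config, file.path(config$out_dir, "config.yaml"))
  logmsg("done")
  invisible(config$out_dir)
}
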