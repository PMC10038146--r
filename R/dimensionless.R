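#' Reference diffusivities (cm^2 s^-1)
#'
#' Effective diffusivity of plankton treated as Brownian walkers (brine
#' shrimp scale), and molecular diffusivities of oxygen and carbon dioxide
#' in seawater.
#'
#' @return Named numeric vector with elements `plankton`, `O2`, `CO2`.
#' @export
diffusivities <- function() {
  c(plankton = 2.5e-3, O2 = 1.97e-5, CO2 = 1.60e-5)
}

#' Reynolds number
#'
#' Re = rho L U / mu with the true fluid viscosity, or L U / nu_nominal with
#' the rounded kinematic viscosity used for integer Re labels (so that a
#' 0.1 cm branch in a 0.2 cm/s stream is labelled Re = 2).
#'
#' @param L characteristic length, cm.
#' @param U characteristic speed, cm s^-1.
#' @param fluid a [fluid_properties()].
#' @param convention `"true"` (rho L U / mu) or `"nominal"` (L U / nu_nominal).
#' @return Re, with the convention recorded as an attribute.
#' @examples
#' reynolds(0.1, 100)               # ~949 with seawater viscosity
#' reynolds(0.1, 0.2, convention = "nominal")  # exactly 2
#' @export
reynolds <- function(L, U, fluid = fluid_properties(),
                     convention = c("true", "nominal")) {
  convention <- match.arg(convention)
  stopifnot(L > 0, U >= 0)
  nu <- if (convention == "true") fluid$kinematic_viscosity
        else fluid$nominal_kinematic_viscosity
  structure(L * U / nu, convention = convention)
}

#' Peclet number
#'
#' Pe = L U / d: the ratio of advective to diffusive (or active-motion)
#' transport for a substance with diffusivity `d`.
#'
#' @param L characteristic length, cm.
#' @param U characteristic speed, cm s^-1.
#' @param d diffusivity, cm^2 s^-1; see [diffusivities()].
#' @return Pe (dimensionless).
#' @examples
#' peclet(0.1, 0.8, diffusivities()[["plankton"]])  # 32
#' @export
peclet <- function(L, U, d) {
  stopifnot(d > 0, L > 0, U >= 0)
  L * U / d
}

#' Porosity proportionality coefficient
#'
#' For porous-sheet models of a whole colony, the slip between fluid and
#' sheet is proportional to the local force with constant Lambda, which can
#' be approximated from the array leakiness as Lambda = Le F / U, where F is
#' the steady force per unit area on the sheet at 90 degrees to the flow.
#'
#' @param Le leakiness of the array.
#' @param F steady force per unit area (dyn cm^-2).
#' @param U free-stream speed (cm s^-1).
#' @return A `porosity_estimate` with element `Lambda`.
#' @export
porosity_coefficient <- function(Le, F, U) {
  stopifnot(U > 0, Le >= 0)
  structure(list(Lambda = Le * F / U, Le = Le, F = F, U = U),
            class = "porosity_estimate")
}

#' @export
print.porosity_estimate <- function(x, ...) {
  cat(sprintf("Porosity coefficient Lambda = Le F / U = %.4g\n", x$Lambda))
  invisible(x)
}

#' Morphometric ratio statistics
#'
#' Per-specimen gap-to-diameter and height-to-diameter summaries from raw
#' gap/diameter(/height) measurements, as used to pick the simulated G/D
#' ranges. Measurements may be calibrated (cm) or in pixels; ratios are
#' unit-free but mixing units within a specimen is an error.
#'
#' @param records data frame with columns `gap` and `diameter` (positive),
#'   optional `height`, optional `specimen` grouping and optional `unit`.
#' @return Data frame with one row per specimen: number of measurements,
#'   mean and sd of G/D (and H/D when heights are present), and the unit.
#' @examples
#' morphometric_summary(data.frame(gap = 0.2, diameter = 0.1))
#' @export
morphometric_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("gap", "diameter") %in% names(records)))
  if (any(records$gap <= 0) || any(records$diameter <= 0)) {
    stop("gap and diameter must be positive", call. = FALSE)
  }
  if (is.null(records$specimen)) records$specimen <- "specimen-1"
  if (is.null(records$unit)) records$unit <- "unknown"
  out <- lapply(split(records, records$specimen), function(s) {
    if (length(unique(s$unit)) > 1) {
      stop(sprintf("specimen '%s' mixes measurement units (%s) without calibration",
                   s$specimen[1], paste(unique(s$unit), collapse = ", ")),
           call. = FALSE)
    }
    gd <- s$gap / s$diameter
    hd <- if (!is.null(s$height)) s$height / s$diameter else NA_real_
    data.frame(specimen = s$specimen[1], n = nrow(s), unit = s$unit[1],
               gd_mean = mean(gd), gd_sd = if (length(gd) > 1) sd(gd) else 0,
               hd_mean = mean(hd),
               hd_sd = if (length(hd) > 1 && !anyNA(hd)) sd(hd) else
                 ifelse(anyNA(hd), NA_real_, 0))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Dimensionless-number report across structural levels
#'
#' Tabulates Re and Pe (per substance) for characteristic length/speed
#' pairs at each structural level, in the style of a feeding-current
#' summary table. Characteristic values are inputs; the defaults cover the
#' four levels at representative ambient speeds.
#'
#' @param levels data frame with columns `level`, `L` (cm), `U` (cm s^-1).
#' @param fluid a [fluid_properties()].
#' @param d named diffusivity vector, see [diffusivities()].
#' @return Data frame with Re under both viscosity conventions and one Pe
#'   column per substance.
#' @export
dimensionless_report <- function(levels = data.frame(
                                   level = c("colony", "branch", "tentacle",
                                             "pinnule"),
                                   L = c(30, 0.1, 0.025, 0.0025),
                                   U = c(10, 0.8, 0.2, 0.1)),
                                 fluid = fluid_properties(),
                                 d = diffusivities()) {
  stopifnot(all(c("level", "L", "U") %in% names(levels)))
  out <- levels
  out$Re_nominal <- levels$L * levels$U / fluid$nominal_kinematic_viscosity
  out$Re_true <- levels$L * levels$U / fluid$kinematic_viscosity
  for (s in names(d)) {
    out[[paste0("Pe_", s)]] <- peclet_vec(levels$L, levels$U, d[[s]])
  }
  out
}

peclet_vec <- function(L, U, d) L * U / d
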