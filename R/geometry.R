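#' Vessel geometry for reduced-order pressure-drop modelling
#'
#' A stenosed epicardial vessel is described as an ordered series of
#' near-cylindrical segments (radius, length) plus an optional focal
#' stenosis characterised by its minimum lumen area, the reference
#' (normal) lumen area, and an expansion loss coefficient. The segment
#' series carries the viscous (Poiseuille) pressure loss; the stenosis
#' carries the additional quadratic loss from post-stenotic flow
#' separation.
#'
#' @param radius_mm numeric vector of segment radii in millimetres.
#' @param length_mm numeric vector of segment lengths in millimetres,
#'   recycled against `radius_mm`.
#' @param stenosis optional stenosis description from [stenosis_spec()].
#' @return an object of class `vessel_geometry` with segment radii/lengths
#'   stored in metres.
#' @seealso [vessel_resistance()], [solve_forward()]
#' @examples
#' g <- vessel_geometry(radius_mm = c(1.5, 0.6, 1.4),
#'                      length_mm = c(20, 10, 40),
#'                      stenosis = stenosis_spec(mld_mm = 1.2, ref_diameter_mm = 2.8))
#' vessel_resistance(g)
#' @export
vessel_geometry <- function(radius_mm, length_mm, stenosis = NULL) {
  if (length(radius_mm) == 0L) stop("geometry needs at least one segment")
  radius_mm <- as.numeric(radius_mm)
  length_mm <- rep_len(as.numeric(length_mm), length(radius_mm))
  if (any(!is.finite(radius_mm)) || any(!is.finite(length_mm)))
    stop("segment radii and lengths must be finite")
  if (any(radius_mm <= 0)) stop("all segment radii must be > 0")
  if (any(length_mm < 0)) stop("segment lengths must be >= 0")
  if (!is.null(stenosis) && !inherits(stenosis, "stenosis_spec"))
    stop("'stenosis' must be built with stenosis_spec()")
  structure(
    list(radius_m = radius_mm * 1e-3,
         length_m = length_mm * 1e-3,
         stenosis = stenosis),
    class = "vessel_geometry"
  )
}

#' Focal stenosis description
#'
#' @param mld_mm minimum lumen diameter (mm).
#' @param ref_diameter_mm reference (normal) lumen diameter at the lesion (mm).
#' @param Ke dimensionless expansion loss coefficient for the post-stenotic
#'   separation loss; the default 1.52 is a standard empirical value for
#'   abrupt expansion in stenosis pressure-drop correlations.
#' @return an object of class `stenosis_spec` carrying the minimum and
#'   reference lumen areas in m^2.
#' @export
stenosis_spec <- function(mld_mm, ref_diameter_mm, Ke = 1.52) {
  stopifnot(is.finite(mld_mm), is.finite(ref_diameter_mm), is.finite(Ke))
  if (mld_mm <= 0 || ref_diameter_mm <= 0) stop("diameters must be > 0")
  if (mld_mm > ref_diameter_mm)
    stop("minimum lumen diameter cannot exceed the reference diameter")
  if (Ke < 0) stop("Ke must be >= 0")
  area <- function(d_mm) pi * (d_mm * 1e-3 / 2)^2
  structure(
    list(area_min = area(mld_mm), area_ref = area(ref_diameter_mm), Ke = Ke),
    class = "stenosis_spec"
  )
}

#' Fluid properties of blood
#'
#' @param viscosity dynamic viscosity in Pa s; the default 3.5e-3 is the
#'   usual Newtonian approximation for blood in large vessels.
#' @param density mass density in kg/m^3.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 3.5e-3, density = 1056) {
  stopifnot(is.finite(viscosity), is.finite(density))
  if (viscosity <= 0 || density <= 0) stop("viscosity and density must be > 0")
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: %d segment(s), total length %.1f mm\n",
              length(x$radius_m), sum(x$length_m) * 1e3))
  if (!is.null(x$stenosis)) {
    d <- function(a) sqrt(4 * a / pi) * 1e3
    cat(sprintf("  stenosis: MLD %.2f mm / ref %.2f mm (%.0f%% diameter stenosis), Ke = %.2f\n",
                d(x$stenosis$area_min), d(x$stenosis$area_ref),
                100 * (1 - d(x$stenosis$area_min) / d(x$stenosis$area_ref)),
                x$stenosis$Ke))
  }
  invisible(x)
}

#' Lumped pressure-drop coefficients of a vessel
#'
#' Collapses the geometry to the two coefficients of the quadratic
#' pressure-drop law `dP = R_v q + S q^2`:
#'
#' * `R_v` is the series Hagen-Poiseuille resistance,
#'   `sum_i 8 h l_i / (pi r_i^4)` (Pa s/m^3), from laminar viscous loss
#'   in each segment;
#' * `S` is the quadratic expansion-loss coefficient
#'   `Ke (rho/2) (1/A_s - 1/A_n)^2` (Pa s^2/m^6), zero without a stenosis
#'   or when the minimum lumen area equals the reference area.
#'
#' @param geometry a [vessel_geometry()].
#' @param fluid a [fluid_properties()].
#' @return named list with elements `R_v` and `S`.
#' @export
vessel_resistance <- function(geometry, fluid = fluid_properties()) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(fluid, "fluid_properties"))
  R_v <- sum(8 * fluid$viscosity * geometry$length_m / (pi * geometry$radius_m^4))
  S <- 0
  st <- geometry$stenosis
  if (!is.null(st))
    S <- st$Ke * (fluid$density / 2) * (1 / st$area_min - 1 / st$area_ref)^2
  list(R_v = R_v, S = S)
}

#' Read and write vessel geometry as JSON
#'
#' The schema is flat:
#' `{"segments": [{"radius_mm": ..., "length_mm": ...}, ...],
#'   "stenosis": {"mld_mm": ..., "ref_diameter_mm": ..., "Ke": ...}}`,
#' with `"stenosis"` optional.
#'
#' @param path file path.
#' @param geometry a [vessel_geometry()].
#' @return `read_geometry_json()` returns a [vessel_geometry()];
#'   `write_geometry_json()` returns `path` invisibly.
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$segments)) stop("geometry JSON lacks a 'segments' field")
  st <- NULL
  if (!is.null(j$stenosis)) {
    ke <- if (is.null(j$stenosis$Ke)) 1.52 else j$stenosis$Ke
    st <- stenosis_spec(j$stenosis$mld_mm, j$stenosis$ref_diameter_mm, Ke = ke)
  }
  vessel_geometry(radius_mm = j$segments$radius_mm,
                  length_mm = j$segments$length_mm,
                  stenosis = st)
}

#' @rdname read_geometry_json
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  out <- list(segments = data.frame(radius_mm = geometry$radius_m * 1e3,
                                    length_mm = geometry$length_m * 1e3))
  st <- geometry$stenosis
  if (!is.null(st)) {
    d <- function(a) sqrt(4 * a / pi) * 1e3
    out$stenosis <- list(mld_mm = d(st$area_min),
                         ref_diameter_mm = d(st$area_ref),
                         Ke = st$Ke)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
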