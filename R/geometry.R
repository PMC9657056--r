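#' Geometry configuration for the idealized implanted femur
#'
#' The femur is idealized as a stack of annular cross-sections along the
#' shaft axis: a cortical annulus around a cancellous core, with the core
#' replaced proximally by a stem plus canal-filling resin in the implanted
#' configurations. Radius profiles are linear in z between the proximal and
#' distal values given.
#'
#' @param working_length Working length of the potted femur in mm (lesser
#'   trochanter to pot), default 328.
#' @param n_stations Number of axial stations (bands) the shaft is split into.
#' @param outer_radius Length-2 numeric: cortical outer radius (mm) at the
#'   proximal and distal ends.
#' @param inner_radius Length-2 numeric: cortical inner (canal) radius (mm) at
#'   the proximal and distal ends.
#' @param stem_tip_z Axial position of the stem tip in mm below the lesser
#'   trochanter.
#' @param stem_radius Length-2 numeric: stem radius (mm) at z = 0 and at the
#'   stem tip.
#'
#' @return A list of class `femur_geometry` echoing the arguments.
#' @export
femur_geometry <- function(working_length = 328, n_stations = 20,
                           outer_radius = c(15.5, 13.5),
                           inner_radius = c(10.5, 8.0),
                           stem_tip_z = 150,
                           stem_radius = c(9.0, 5.0)) {
  stopifnot(working_length > 0, n_stations >= 2,
            length(outer_radius) == 2L, length(inner_radius) == 2L,
            length(stem_radius) == 2L)
  if (any(outer_radius <= inner_radius))
    stop("cortical outer radius must exceed inner radius")
  if (any(inner_radius <= 0) || any(stem_radius <= 0))
    stop("radii must be positive")
  if (stem_tip_z <= 0 || stem_tip_z >= working_length)
    stop("stem_tip_z must lie strictly inside the working length")
  structure(
    list(working_length = working_length, n_stations = n_stations,
         outer_radius = outer_radius, inner_radius = inner_radius,
         stem_tip_z = stem_tip_z, stem_radius = stem_radius),
    class = "femur_geometry")
}

lin_profile <- function(ends, z, z_end) ends[1] + (ends[2] - ends[1]) * z / z_end

annulus_area <- function(r_out, r_in = 0) pi * (r_out^2 - r_in^2)
annulus_inertia <- function(r_out, r_in = 0) pi * (r_out^4 - r_in^4) / 4

#' Build a stacked cross-section model of the (implanted) femur
#'
#' Produces one station per axial band. Every station has exactly one
#' cortical annulus; intact configurations carry a cancellous core, while
#' implanted configurations replace the core proximal to the stem tip with a
#' stem circle plus a resin annulus filling the canal (distal stations are
#' identical to the intact model, which is what makes the distal Gruen zone
#' insensitive to the implant).
#'
#' @param geometry A [femur_geometry()] object.
#' @param configuration `"intact"` or `"implanted"`.
#' @param stem_material Material name for the stem regions (implanted only),
#'   e.g. `"Ti6Al4V"` or `"PEEK"`.
#'
#' @return An object of class `cross_section_model`: a list with `stations`
#'   (each holding `z`, band width `dz`, and a `regions` data frame with
#'   material, area (mm^2), second moments about both bending axes (mm^4),
#'   inner/outer radii and a surface flag) plus the geometry metadata.
#' @export
build_geometry <- function(geometry = femur_geometry(),
                           configuration = c("intact", "implanted"),
                           stem_material = "Ti6Al4V") {
  configuration <- match.arg(configuration)
  g <- geometry
  dz <- g$working_length / g$n_stations
  z_centers <- (seq_len(g$n_stations) - 0.5) * dz

  stations <- lapply(z_centers, function(z) {
    r_out <- lin_profile(g$outer_radius, z, g$working_length)
    r_in <- lin_profile(g$inner_radius, z, g$working_length)
    regions <- data.frame(
      material = "cortical",
      area = annulus_area(r_out, r_in),
      i_x = annulus_inertia(r_out, r_in),
      i_y = annulus_inertia(r_out, r_in),
      r_in = r_in, r_out = r_out,
      surface = "cortex",
      stringsAsFactors = FALSE)
    implanted_here <- configuration == "implanted" && z < g$stem_tip_z
    if (implanted_here) {
      r_s <- lin_profile(g$stem_radius, z, g$stem_tip_z)
      if (r_s >= r_in)
        stop("geometry infeasible: stem radius ", round(r_s, 2),
             " mm >= canal radius ", round(r_in, 2), " mm at z = ",
             round(z, 1), " mm")
      regions <- rbind(regions, data.frame(
        material = c(stem_material, "resin"),
        area = c(annulus_area(r_s), annulus_area(r_in, r_s)),
        i_x = c(annulus_inertia(r_s), annulus_inertia(r_in, r_s)),
        i_y = c(annulus_inertia(r_s), annulus_inertia(r_in, r_s)),
        r_in = c(0, r_s), r_out = c(r_s, r_in),
        surface = "interior",
        stringsAsFactors = FALSE))
    } else {
      regions <- rbind(regions, data.frame(
        material = "cancellous",
        area = annulus_area(r_in),
        i_x = annulus_inertia(r_in),
        i_y = annulus_inertia(r_in),
        r_in = 0, r_out = r_in,
        surface = "interior",
        stringsAsFactors = FALSE))
    }
    list(z = z, dz = dz, regions = regions)
  })

  structure(
    list(stations = stations,
         working_length = g$working_length,
         stem_tip_z = if (configuration == "implanted") g$stem_tip_z else NA_real_,
         configuration = configuration,
         stem_material = if (configuration == "implanted") stem_material else NA_character_),
    class = "cross_section_model")
}

#' Modulus-weighted rigidity of one cross-section
#'
#' Composite-section axial and bending rigidities: sums of E*A and E*I over
#' the station's regions.
#'
#' @param station One element of a [build_geometry()] model's `stations` list.
#' @param materials Named list of [material_spec()] objects.
#' @return Named numeric vector `c(EA, EI_x, EI_y)` in N and N mm^2.
#' @export
section_stiffness <- function(station, materials) {
  E <- vapply(station$regions$material,
              function(nm) resolve_material(nm, materials)$youngs_modulus,
              numeric(1))
  out <- c(EA = sum(E * station$regions$area),
           EI_x = sum(E * station$regions$i_x),
           EI_y = sum(E * station$regions$i_y))
  if (any(out <= 0)) stop("section rigidity must be strictly positive")
  out
}
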