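#' Define an isotropic linear-elastic material
#'
#' Materials carry the elastic constants used by the composite-beam femur
#' model plus the optional strength constants used by the fatigue analysis.
#'
#' @param name Material name (used to resolve regions of a cross-section).
#' @param youngs_modulus Young's modulus E in MPa. Must be positive.
#' @param poisson_ratio Poisson's ratio, in `[0, 0.5)`.
#' @param density Mass density in g/mL. Must be positive.
#' @param yield_strength Optional yield strength in MPa.
#' @param endurance_limit Optional endurance limit in MPa (stress amplitude
#'   survived at the qualification cycle count).
#'
#' @return An object of class `material_spec`.
#' @export
#' @examples
#' material_spec("PEEK", 1690, 0.35, 1.30, yield_strength = 85.5,
#'               endurance_limit = 70)
material_spec <- function(name, youngs_modulus, poisson_ratio, density,
                          yield_strength = NULL, endurance_limit = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0 (MPa)")
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5)")
  if (!is.numeric(density) || density <= 0)
    stop("density must be > 0 (g/mL)")
  if (!is.null(yield_strength) && yield_strength <= 0)
    stop("yield_strength, when given, must be > 0 (MPa)")
  if (!is.null(endurance_limit) && endurance_limit <= 0)
    stop("endurance_limit, when given, must be > 0 (MPa)")
  structure(
    list(name = name,
         youngs_modulus = youngs_modulus,
         poisson_ratio = poisson_ratio,
         density = density,
         yield_strength = yield_strength,
         endurance_limit = endurance_limit),
    class = "material_spec")
}

#' Default material set for the synthetic implanted femur
#'
#' Cortical shell 16.7 GPa / nu 0.3 / 1.64 g/mL, cancellous core 0.155 GPa /
#' 0.3 / 0.27 g/mL, canal-filling epoxy resin 2.5 GPa / 0.3, Ti6Al4V stem
#' 110 GPa / 0.3, and PEEK stem 1.69 GPa / 0.35 with yield strength 85.5 MPa
#' and endurance limit 70 MPa (5e6-cycle qualification).
#'
#' @return Named list of [material_spec()] objects keyed by material name.
#' @export
default_materials <- function() {
  mats <- list(
    material_spec("cortical",   16700, 0.30, 1.64),
    material_spec("cancellous",   155, 0.30, 0.27),
    material_spec("resin",       2500, 0.30, 1.69),
    material_spec("Ti6Al4V",   110000, 0.30, 4.43, yield_strength = 880),
    material_spec("PEEK",        1690, 0.35, 1.30, yield_strength = 85.5,
                  endurance_limit = 70)
  )
  stats::setNames(mats, vapply(mats, `[[`, character(1), "name"))
}

resolve_material <- function(name, materials) {
  m <- materials[[name]]
  if (is.null(m)) stop("unknown material name: ", name)
  m
}

#' Define a hip load case
#'
#' An axial compressive load applied through the femoral head, tilted in the
#' coronal and sagittal planes per the ISO 7206-4 setup (10 degrees adduction,
#' 9 degrees flexion by default). The head offset is the lever arm from the
#' shaft axis to the point of load application, in the model frame
#' (x lateral-to-medial, y posterior-to-anterior, z distal from the lesser
#' trochanter).
#'
#' @param magnitude Load magnitude in N, >= 0.
#' @param adduction_deg Coronal-plane tilt in degrees, in `[0, 30]`.
#' @param flexion_deg Sagittal-plane tilt in degrees, in `[0, 30]`.
#' @param head_offset Numeric length-3 vector (mm): load application point
#'   relative to the shaft axis origin at the lesser trochanter.
#'
#' @return An object of class `load_case`.
#' @export
load_case <- function(magnitude, adduction_deg = 10, flexion_deg = 9,
                      head_offset = c(40, 0, -60)) {
  if (!is.numeric(magnitude) || magnitude < 0)
    stop("load magnitude must be >= 0 (N)")
  if (adduction_deg < 0 || adduction_deg > 30 ||
      flexion_deg < 0 || flexion_deg > 30)
    stop("adduction and flexion angles must lie in [0, 30] degrees")
  stopifnot(is.numeric(head_offset), length(head_offset) == 3L)
  structure(
    list(magnitude = magnitude,
         adduction_deg = adduction_deg,
         flexion_deg = flexion_deg,
         head_offset = as.numeric(head_offset)),
    class = "load_case")
}

#' Nominal porosity of an orthogonal rectilinear lattice
#'
#' Open fraction of one lattice period: `pore / (pore + strut)`. A 0.4 mm
#' pore with a 0.4 mm strut gives the 50% nominal porosity of the stem's
#' surface scaffold.
#'
#' @param pore_size Pore size in mm, >= 0.
#' @param strut_size Strut size in mm, > 0.
#' @return Porosity as a fraction in `[0, 1)`.
#' @export
#' @examples
#' nominal_porosity(0.4, 0.4)  # 0.5
nominal_porosity <- function(pore_size, strut_size) {
  if (!is.numeric(pore_size) || pore_size < 0)
    stop("pore_size must be >= 0")
  if (!is.numeric(strut_size) || strut_size <= 0)
    stop("strut_size must be > 0")
  pore_size / (pore_size + strut_size)
}
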