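#' Element stress/strain fields from the composite-beam femur model
#'
#' Resolves a hip load case into an axial force plus bending moments and
#' evaluates the classical composite-beam strain field
#' `eps(x, y, z) = N/EA + (M_y/EI_y) x - (M_x/EI_x) y`
#' at material points laid out on each cross-section (strain compatibility:
#' all materials at a point share the section strain; stress is E_i * eps).
#' The stress state is uniaxial, so the von Mises stress is `|E * eps|`. The
#' signed principal compressive strain is `eps` where the fiber is in
#' compression and the Poisson transverse strain `-nu * eps` where it is in
#' tension. Multiplicative Gaussian noise (one factor per element, fixed by
#' `seed`) emulates discretization scatter in the reference fields.
#'
#' @param model A [build_geometry()] cross-section model.
#' @param load A [load_case()].
#' @param materials Named list of [material_spec()] objects.
#' @param mesh_density Angular mesh refinement: each region is sampled at
#'   `4 * mesh_density` circumferential points per station. Must be >= 1.
#' @param noise_sd Relative standard deviation of the multiplicative noise
#'   (0 disables it). Must be >= 0.
#' @param seed Integer seed making the noise reproducible.
#'
#' @return A data frame (element field table) with columns `element_id`,
#'   `zone` (NA until [assign_gruen_zones()] is applied), `z`, `side`
#'   (`medial`/`lateral` for cortical fibers, `interior` otherwise), `volume`
#'   (mm^3), `density` (g/mL), `vm_stress` (MPa), `comp_strain` (signed),
#'   plus generator columns `material`, `x`, `y`, `axial_strain`.
#' @export
beam_fields <- function(model, load, materials = default_materials(),
                        mesh_density = 4, noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(model, "cross_section_model"), inherits(load, "load_case"))
  if (mesh_density < 1) stop("mesh_density must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  a <- load$adduction_deg * pi / 180
  b <- load$flexion_deg * pi / 180
  P <- load$magnitude
  # adduction applied before flexion; z distal, x lateral->medial, y post->ant
  F <- P * c(sin(a), cos(a) * sin(b), cos(a) * cos(b))
  p0 <- load$head_offset
  n_ang <- 4L * as.integer(mesh_density)
  theta <- (seq_len(n_ang) - 0.5) * 2 * pi / n_ang

  rows <- vector("list", length(model$stations))
  for (k in seq_along(model$stations)) {
    st <- model$stations[[k]]
    rig <- section_stiffness(st, materials)
    r_lever <- p0 - c(0, 0, st$z)
    m_x <- r_lever[2] * F[3] - r_lever[3] * F[2]
    m_y <- r_lever[3] * F[1] - r_lever[1] * F[3]
    axial <- -F[3] / rig[["EA"]]

    reg <- st$regions
    per_reg <- vector("list", nrow(reg))
    for (j in seq_len(nrow(reg))) {
      if (reg$surface[j] == "cortex") {
        r_rep <- (reg$r_in[j] + reg$r_out[j]) / 2
      } else if (reg$r_in[j] == 0) {
        r_rep <- reg$r_out[j] / sqrt(2)   # RMS radius of a filled circle
      } else {
        r_rep <- (reg$r_in[j] + reg$r_out[j]) / 2
      }
      x <- r_rep * cos(theta)
      y <- r_rep * sin(theta)
      eps <- axial + (m_y / rig[["EI_y"]]) * x - (m_x / rig[["EI_x"]]) * y
      mat <- resolve_material(reg$material[j], materials)
      side <- if (reg$surface[j] == "cortex")
        ifelse(x >= 0, "medial", "lateral") else rep("interior", n_ang)
      per_reg[[j]] <- data.frame(
        zone = NA_integer_,
        z = st$z,
        side = side,
        volume = reg$area[j] * st$dz / n_ang,
        density = mat$density,
        vm_stress = abs(mat$youngs_modulus * eps),
        comp_strain = ifelse(eps < 0, eps, -mat$poisson_ratio * eps),
        material = reg$material[j],
        x = x, y = y,
        axial_strain = eps,
        stringsAsFactors = FALSE)
    }
    rows[[k]] <- do.call(rbind, per_reg)
  }
  tab <- do.call(rbind, rows)
  # cortical fibers first so their ids are stable across configurations
  # (interior regions differ between intact and implanted models)
  tab <- rbind(tab[tab$side != "interior", ], tab[tab$side == "interior", ])
  tab <- cbind(element_id = seq_len(nrow(tab)), tab)

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    f <- 1 + noise_sd * stats::rnorm(nrow(tab))
    f <- pmax(f, 0.01)  # keep the multiplicative factor positive
    tab$vm_stress <- tab$vm_stress * f
    tab$comp_strain <- tab$comp_strain * f
    tab$axial_strain <- tab$axial_strain * f
  }
  rownames(tab) <- NULL
  tab
}

#' Label elements with Gruen zones
#'
#' Lateral cortical fibers are split proximal-to-distal into zones 1, 2, 3
#' and medial fibers into the mirror zones 7, 6, 5; everything distal to the
#' stem tip is zone 4 regardless of side. Band edges default to thirds of the
#' stem length. Interior (non-cortical) elements receive the positional label
#' of the medial numbering; they are excluded from every cortical aggregate
#' by their `side` flag, so the label is informational only.
#'
#' @param table An element field table from [beam_fields()].
#' @param stem_tip_z Stem tip position in mm.
#' @param band_edges Increasing numeric length-2 vector of band edges (mm);
#'   default `stem_tip_z * c(1, 2) / 3`.
#' @param working_length Optional working length used to validate `z`.
#' @return The table with its `zone` column filled (integer 1-7).
#' @export
assign_gruen_zones <- function(table, stem_tip_z, band_edges = NULL,
                               working_length = NULL) {
  if (is.null(band_edges)) band_edges <- stem_tip_z * c(1, 2) / 3
  stopifnot(length(band_edges) == 2L, diff(band_edges) > 0,
            band_edges[1] > 0, band_edges[2] < stem_tip_z)
  if (any(table$z < 0))
    stop("element z below 0: cannot label Gruen zones")
  if (!is.null(working_length) && any(table$z > working_length))
    stop("element z beyond the working length: cannot label Gruen zones")

  band <- findInterval(table$z, c(band_edges, stem_tip_z)) + 1L  # 1,2,3,4
  lateral_zone <- c(1L, 2L, 3L)
  medial_zone <- c(7L, 6L, 5L)
  zone <- integer(nrow(table))
  distal <- band == 4L
  zone[distal] <- 4L
  lat <- !distal & table$side == "lateral"
  med <- !distal & table$side != "lateral"
  zone[lat] <- lateral_zone[band[lat]]
  zone[med] <- medial_zone[band[med]]
  table$zone <- zone
  table
}

#' Generate paired intact/implanted element fields
#'
#' Builds the intact and implanted cross-section models on the same geometry,
#' evaluates both stress fields under the same load (with independent noise
#' draws, as two independent analyses would have), labels Gruen zones, and
#' returns the cortical elements as an aligned pair. Because the geometry is
#' shared, cortical elements carry identical ids, volumes, zones and
#' densities in the two tables. The implanted model's stem elements are kept
#' alongside for the safety analysis.
#'
#' @param geometry A [femur_geometry()].
#' @param stem_material `"Ti6Al4V"` or `"PEEK"` (any material name resolvable
#'   in `materials`).
#' @param load A [load_case()].
#' @param materials Named list of [material_spec()] objects.
#' @param mesh_density,noise_sd Passed to [beam_fields()].
#' @param seed Integer master seed; the two configurations draw independent
#'   sub-seeds from it.
#' @param band_edges Optional Gruen band edges, see [assign_gruen_zones()].
#'
#' @return An object of class `paired_fields`: list with `intact` and
#'   `implanted` cortical element tables, `stem_field` (the implanted model's
#'   stem elements), and `stem_material`.
#' @export
generate_paired_fields <- function(geometry = femur_geometry(),
                                   stem_material = "Ti6Al4V",
                                   load = load_case(2300),
                                   materials = default_materials(),
                                   mesh_density = 4, noise_sd = 0.02,
                                   seed = 1L, band_edges = NULL) {
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  m_int <- build_geometry(geometry, "intact")
  m_imp <- build_geometry(geometry, "implanted", stem_material = stem_material)
  t_int <- beam_fields(m_int, load, materials, mesh_density, noise_sd, sub_seeds[1])
  t_imp <- beam_fields(m_imp, load, materials, mesh_density, noise_sd, sub_seeds[2])
  t_int <- assign_gruen_zones(t_int, geometry$stem_tip_z, band_edges,
                              geometry$working_length)
  t_imp <- assign_gruen_zones(t_imp, geometry$stem_tip_z, band_edges,
                              geometry$working_length)

  paired_fields(t_int[t_int$side != "interior", ],
                t_imp[t_imp$side != "interior", ],
                stem_material = stem_material,
                stem_field = t_imp[t_imp$material == stem_material, ])
}

#' Construct an aligned intact/implanted field pair
#'
#' Validates that the two tables describe the same cortical elements:
#' identical id sets and identical per-element volume, zone and density.
#'
#' @param intact,implanted Element field tables (cortical elements).
#' @param stem_material Stem material name carried as metadata.
#' @param stem_field Optional table of the implanted model's stem elements.
#' @return An object of class `paired_fields`.
#' @export
paired_fields <- function(intact, implanted, stem_material = NA_character_,
                          stem_field = NULL) {
  if (nrow(intact) != nrow(implanted))
    stop("paired tables must have the same number of elements")
  o1 <- order(intact$element_id); o2 <- order(implanted$element_id)
  intact <- intact[o1, ]; implanted <- implanted[o2, ]
  if (!identical(intact$element_id, implanted$element_id))
    stop("paired tables must share the same element_id set")
  same <- function(col) isTRUE(all.equal(intact[[col]], implanted[[col]],
                                         tolerance = 1e-12))
  for (col in c("volume", "zone", "density"))
    if (!same(col)) stop("paired tables disagree on per-element ", col)
  structure(list(intact = intact, implanted = implanted,
                 stem_material = stem_material, stem_field = stem_field),
            class = "paired_fields")
}

#' Default strain-rosette sites on the femoral shaft
#'
#' Four lateral sites L1-L4 at 0, 31.75, 63.5 and 95.25 mm below the lesser
#' trochanter, and six medial sites M1, MX1, M2, MX2, M3, M4 at 0, 16, 31.75,
#' 47.75, 63.5 and 95.25 mm.
#'
#' @return Data frame with columns `site`, `side`, `z`.
#' @export
default_gauge_sites <- function() {
  data.frame(
    site = c("L1", "L2", "L3", "L4", "M1", "MX1", "M2", "MX2", "M3", "M4"),
    side = c(rep("lateral", 4), rep("medial", 6)),
    z = c(0, 31.75, 63.5, 95.25, 0, 16, 31.75, 47.75, 63.5, 95.25),
    stringsAsFactors = FALSE)
}

#' Simulate 45-degree rosette readings at gauge sites
#'
#' Picks, for each requested site, the cortical surface element nearest the
#' site's axial position on the requested side (preferring the extreme
#' coronal fiber) and renders its uniaxial surface state as three rosette
#' channels with gauge A parallel to the shaft axis: `eA = eps_axial`,
#' `eC = -nu * eps_axial` (Poisson hoop strain), `eB = (eA + eC) / 2`
#' (no shear on the gauge axes).
#'
#' @param table An element field table carrying the generator's
#'   `axial_strain` column.
#' @param sites Data frame of sites (`site`, `side`, `z`); defaults to the
#'   ten shaft sites of [default_gauge_sites()].
#' @param nu Poisson's ratio of the surface material (cortical 0.3).
#' @param tol Maximum axial distance (mm) between a site and its element.
#' @return Data frame with one row per site: `site`, `side`, `z`,
#'   `element_id`, `eA_ue`, `eB_ue`, `eC_ue` (microstrain).
#' @export
sample_gauge_sites <- function(table, sites = default_gauge_sites(),
                               nu = 0.3, tol = 12) {
  if (is.null(table$axial_strain))
    stop("table lacks the generator's axial_strain column")
  surf <- table[table$side %in% c("medial", "lateral"), ]
  out <- lapply(seq_len(nrow(sites)), function(i) {
    cand <- surf[surf$side == sites$side[i], ]
    if (nrow(cand) == 0) stop("no surface elements on side ", sites$side[i])
    dz <- abs(cand$z - sites$z[i])
    if (min(dz) > tol)
      stop("no surface element within ", tol, " mm of site ", sites$site[i])
    cand <- cand[dz == min(dz), ]
    cand <- cand[order(-abs(cand$x), cand$element_id), ][1, ]
    eA <- cand$axial_strain * 1e6
    eC <- -nu * eA
    data.frame(site = sites$site[i], side = sites$side[i], z = sites$z[i],
               element_id = cand$element_id,
               eA_ue = eA, eB_ue = (eA + eC) / 2, eC_ue = eC,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

field_csv_cols <- c(element_id = "element_id", zone = "zone", z = "z_mm",
                    side = "side", volume = "volume_mm3",
                    density = "density_g_per_ml", vm_stress = "vm_stress_mpa",
                    comp_strain = "comp_strain", material = "material")

#' Write / read an element field table as CSV
#'
#' The interchange dialect uses explicit units in the column names:
#' `element_id, zone, z_mm, side, volume_mm3, density_g_per_ml,
#' vm_stress_mpa, comp_strain, material`.
#'
#' @param table Element field table.
#' @param path File path.
#' @return `read_field_csv` returns the table with internal column names.
#' @export
write_field_csv <- function(table, path) {
  out <- table[, names(field_csv_cols)]
  names(out) <- unname(field_csv_cols)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(field_csv_cols), names(raw))
  if (length(missing))
    stop("field CSV lacks required columns: ", paste(missing, collapse = ", "))
  out <- raw[, unname(field_csv_cols)]
  names(out) <- names(field_csv_cols)
  out
}
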