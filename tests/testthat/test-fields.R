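test_that("zero load produces identically zero fields", {
  m <- build_geometry(femur_geometry(n_stations = 6))
  tab <- beam_fields(m, load_case(0), mesh_density = 2, noise_sd = 0.02,
                     seed = 7)
  expect_true(all(tab$vm_stress == 0))
  expect_true(all(tab$comp_strain == 0))
})

test_that("fields scale exactly with load magnitude at fixed seed", {
  m <- build_geometry(femur_geometry(n_stations = 6), "implanted")
  t1 <- beam_fields(m, load_case(1200), mesh_density = 2, seed = 3)
  t2 <- beam_fields(m, load_case(2400), mesh_density = 2, seed = 3)
  expect_equal(t2$vm_stress, 2 * t1$vm_stress, tolerance = 1e-12)
  expect_equal(t2$comp_strain, 2 * t1$comp_strain, tolerance = 1e-12)
})

test_that("pure axial load on a single-material bar recovers sigma = P/A", {
  A <- 123.4; E <- 2000; P <- 1500
  m <- bar_model(area = A)
  ld <- load_case(P, adduction_deg = 0, flexion_deg = 0,
                  head_offset = c(0, 0, -10))
  tab <- beam_fields(m, ld, bar_materials(E), mesh_density = 4, noise_sd = 0)
  expect_equal(tab$vm_stress, rep(P / A, nrow(tab)), tolerance = 1e-12)
  expect_equal(tab$comp_strain, rep(-P / (E * A), nrow(tab)),
               tolerance = 1e-12)
})

test_that("identical seed and config reproduce the table exactly", {
  m <- build_geometry(femur_geometry(n_stations = 6), "implanted")
  t1 <- beam_fields(m, load_case(2300), mesh_density = 2, seed = 11)
  t2 <- beam_fields(m, load_case(2300), mesh_density = 2, seed = 11)
  expect_identical(t1, t2)
  t3 <- beam_fields(m, load_case(2300), mesh_density = 2, seed = 12)
  expect_false(identical(t1$vm_stress, t3$vm_stress))
})

test_that("stiffer stems shield the proximal cortex more", {
  g <- femur_geometry()
  ld <- load_case(2300)
  mats <- default_materials()
  station_means <- function(config, stem) {
    m <- build_geometry(g, config, stem_material = stem)
    tab <- beam_fields(m, ld, mats, mesh_density = 2, noise_sd = 0)
    cort <- tab[tab$side != "interior" & tab$z < g$stem_tip_z, ]
    tapply(cort$vm_stress, cort$z, mean)
  }
  intact <- station_means("intact")
  ti <- station_means("implanted", "Ti6Al4V")
  peek <- station_means("implanted", "PEEK")
  expect_true(all(ti < peek))
  expect_true(all(peek <= intact + 1e-12))
})

test_that("elements distal to the stem tip are untouched by implantation", {
  g <- femur_geometry(stem_tip_z = 150)
  ld <- load_case(2300)
  ti <- beam_fields(build_geometry(g, "intact"), ld, mesh_density = 2,
                    noise_sd = 0)
  tp <- beam_fields(build_geometry(g, "implanted"), ld, mesh_density = 2,
                    noise_sd = 0)
  cort_i <- ti[ti$side != "interior" & ti$z > g$stem_tip_z, ]
  cort_p <- tp[tp$side != "interior" & tp$z > g$stem_tip_z, ]
  expect_equal(cort_i$vm_stress, cort_p$vm_stress, tolerance = 1e-12)
})

test_that("Gruen zone labels follow side and axial band", {
  tab <- data.frame(
    element_id = 1:8,
    zone = NA_integer_,
    z = c(10, 60, 120, 200, 10, 60, 120, 200),
    side = c(rep("lateral", 4), rep("medial", 4)),
    stringsAsFactors = FALSE)
  out <- assign_gruen_zones(tab, stem_tip_z = 150)
  expect_equal(out$zone, c(1L, 2L, 3L, 4L, 7L, 6L, 5L, 4L))
  expect_error(assign_gruen_zones(transform(tab, z = z - 20), 150), "below 0")
  expect_error(assign_gruen_zones(tab, 150, working_length = 150),
               "working length")
})

test_that("rosette sampling returns the ten canonical shaft sites", {
  m <- build_geometry(femur_geometry(), "intact")
  tab <- beam_fields(m, load_case(1200), mesh_density = 2, noise_sd = 0)
  g <- sample_gauge_sites(tab)
  expect_equal(nrow(g), 10L)
  expect_setequal(g$site, c("L1", "L2", "L3", "L4", "M1", "M2", "M3", "M4",
                            "MX1", "MX2"))
  # medial fibers compress axially under this load, lateral ones extend
  expect_true(all(g$eA_ue[g$side == "medial"] < 0))
  expect_true(all(g$eA_ue[g$side == "lateral"] > 0))
})

test_that("sampled rosette channels follow the uniaxial surface state", {
  m <- build_geometry(femur_geometry(), "intact")
  tab <- beam_fields(m, load_case(1200), mesh_density = 2, noise_sd = 0)
  # with nu = 0 the channels collapse to (e, e/2, 0)
  g0 <- sample_gauge_sites(tab, nu = 0)
  expect_equal(g0$eB_ue, g0$eA_ue / 2, tolerance = 1e-12)
  expect_equal(g0$eC_ue, rep(0, 10), tolerance = 1e-12)
  # zero field reads zero everywhere
  gz <- sample_gauge_sites(beam_fields(m, load_case(0), mesh_density = 2,
                                       noise_sd = 0))
  expect_true(all(gz$eA_ue == 0 & gz$eB_ue == 0 & gz$eC_ue == 0))
  # a site far from any station is a sampling error
  far <- data.frame(site = "X", side = "medial", z = 1e4)
  expect_error(sample_gauge_sites(tab, far), "within")
})

test_that("nominal lattice porosity is the open fraction of the period", {
  expect_equal(nominal_porosity(0.4, 0.4), 0.5)
  expect_equal(nominal_porosity(0, 0.4), 0)
  expect_equal(nominal_porosity(0.6, 0.2), 0.75)
  expect_error(nominal_porosity(-0.1, 0.4), ">= 0")
  expect_error(nominal_porosity(0.4, 0), "> 0")
})

test_that("field tables survive the CSV round trip", {
  m <- build_geometry(femur_geometry(n_stations = 4), "implanted")
  tab <- beam_fields(m, load_case(2300), mesh_density = 1, seed = 5)
  tab <- assign_gruen_zones(tab, 150)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(tab, path)
  back <- read_field_csv(path)
  for (col in c("element_id", "zone", "side", "material"))
    expect_identical(back[[col]], tab[[col]])
  for (col in c("z", "volume", "density", "vm_stress", "comp_strain"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
})
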