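test_that("strain-energy ratio squares the strain ratio and guards the floor", {
  expect_equal(strain_energy_ratio(-1e-3, -1e-3), 1)
  expect_equal(strain_energy_ratio(0, -1e-3), 0)
  expect_equal(strain_energy_ratio(-5e-4, -1e-3), 0.25)
  # sign is removed by squaring
  expect_equal(strain_energy_ratio(5e-4, -1e-3), 0.25)
  # unloaded intact elements are excluded, not divided
  out <- strain_energy_ratio(c(-1e-3, -1e-3), c(0, -1e-12))
  expect_true(all(is.na(out)))
})

test_that("dead-zone indicator fires only below (1 - s) of intact energy", {
  p <- remodeling_params(dead_zone_s = 0.6)
  expect_equal(resorption_indicator(1, p), 0L)      # inside the dead zone
  expect_equal(resorption_indicator(0, p), 1L)      # full unloading resorbs
  expect_equal(resorption_indicator(0.25, p), 1L)   # 0.25 < 0.4
  expect_equal(resorption_indicator(0.4, p), 0L)    # boundary: x = 1 holds
  expect_equal(resorption_indicator(0.39999, p), 1L)
  expect_error(resorption_indicator(-0.1, p), ">= 0")
  expect_error(remodeling_params(dead_zone_s = 1), "0, 1")
})

test_that("resorbed mass fraction is the mass-weighted indicator mean", {
  all_on <- planted_pair(1)
  expect_equal(resorbed_mass_fraction(all_on, 1)$resorbed_mass_fraction, 1)
  all_off <- planted_pair(0)
  expect_equal(resorbed_mass_fraction(all_off, 1)$resorbed_mass_fraction, 0)
  half <- planted_pair(0.5, n = 2)
  r <- resorbed_mass_fraction(half, 1)
  expect_equal(r$resorbed_mass_fraction, 0.5)
  expect_equal(r$resorbing_mass, r$total_mass / 2)
  expect_equal(r$excluded_elements, 0L)
})

test_that("excluded elements leave both sums and are counted", {
  pr <- planted_pair(0.5, n = 4)
  pr$intact$comp_strain[1] <- 0           # unloaded in the intact field
  pr$implanted$comp_strain[1] <- 0
  r <- resorbed_mass_fraction(pr, 1)
  expect_equal(r$excluded_elements, 1L)
  # one resorbing of three valid equal-mass elements
  expect_equal(r$resorbed_mass_fraction, 1 / 3)

  dead <- planted_pair(0, n = 2)
  dead$intact$comp_strain[] <- 0
  expect_error(resorbed_mass_fraction(dead, 1), "excluded")
})

test_that("resorbed fraction is non-increasing in the dead-zone width", {
  # threshold (1 - s) shrinks as s grows, so fewer elements resorb
  set.seed(1)
  n <- 40
  intact <- make_table(n, comp_strain = -1e-3)
  implanted <- intact
  implanted$comp_strain <- intact$comp_strain * runif(n, 0, 1)
  pr <- paired_fields(intact, implanted)
  mr <- vapply(c(0.3, 0.6, 0.9), function(s)
    resorbed_mass_fraction(pr, 1, remodeling_params(s))$resorbed_mass_fraction,
    numeric(1))
  expect_true(all(diff(mr) <= 0))
  expect_true(mr[1] > mr[3])  # strict somewhere on this field
})

test_that("bone loss reduction compares stems and is NA at zero reference", {
  expect_equal(bone_loss_reduction(0.4, 0.4), 0)
  expect_equal(bone_loss_reduction(0.4, 0), 1)
  expect_equal(bone_loss_reduction(0.4, 0.1), 0.75)
  expect_true(is.na(bone_loss_reduction(0, 0.1)))
})

test_that("stiff stems resorb at least as much proximal bone as compliant ones", {
  g <- femur_geometry()
  ld <- load_case(2300)
  pr_ti <- generate_paired_fields(g, "Ti6Al4V", ld, mesh_density = 2, seed = 5)
  pr_pk <- generate_paired_fields(g, "PEEK", ld, mesh_density = 2, seed = 5)
  for (z in c(1, 2, 6, 7)) {
    expect_gte(resorbed_mass_fraction(pr_ti, z)$resorbed_mass_fraction,
               resorbed_mass_fraction(pr_pk, z)$resorbed_mass_fraction)
  }
  rep_ti <- resorption_report(pr_ti)
  expect_gte(attr(rep_ti, "total"), attr(resorption_report(pr_pk), "total"))
  # volume weighting is available and bounded like the mass weighting
  tot_v <- attr(resorption_report(pr_ti, weighting = "volume"), "total")
  expect_true(tot_v >= 0 && tot_v <= 1)
})
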