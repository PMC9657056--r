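test_that("yield FoS is yield strength over peak stress", {
  expect_equal(round_half_up(yield_fos(82.3, 85.5), 2), 1.04)
  expect_equal(round_half_up(yield_fos(76, 85.5), 2), 1.13)
  expect_equal(yield_fos(85.5, 85.5), 1)
  expect_identical(yield_fos(0, 85.5), Inf)
})

test_that("cyclic stresses follow the proportional cycle decomposition", {
  p <- fatigue_params(stress_ratio_R = 0.1)
  c76 <- cyclic_stresses(76, p)
  expect_equal(c76$sigma_min, 7.6)
  expect_equal(c76$sigma_m, 41.8)
  expect_equal(c76$sigma_a, 34.2)

  static <- cyclic_stresses(50, fatigue_params(1, 85.5, 70))
  expect_equal(static$sigma_a, 0)
  expect_equal(static$sigma_m, 50)

  rev <- cyclic_stresses(100, fatigue_params(0, 85.5, 70))
  expect_equal(c(rev$sigma_m, rev$sigma_a), c(50, 50))
  expect_error(cyclic_stresses(-1, p), ">= 0")
})

test_that("Soderberg FoS hits the endurance and yield anchors", {
  p <- fatigue_params(0.1, 85.5, 70)
  expect_equal(round(soderberg_fos(34.2, 41.8, p), 3), 1.023)
  expect_equal(soderberg_fos(0, 85.5, p), 1)   # static yield limit
  expect_equal(soderberg_fos(70, 0, p), 1)     # endurance limit
  expect_identical(soderberg_fos(0, 0, p), Inf)
  expect_error(fatigue_params(0.1, 85.5, 90), "sigma_N")
})

test_that("safety map composes the per-element chain", {
  p <- fatigue_params(0.1, 85.5, 70)
  uni <- make_table(5, vm_stress = 85.5)
  m <- safety_map(uni, p)
  expect_equal(m$fos_yield, rep(1, 5))

  one <- make_table(1, vm_stress = 76)
  row <- safety_map(one, p)
  expect_equal(row$sigma_m, 41.8)
  expect_equal(row$sigma_a, 34.2)
  expect_equal(round_half_up(row$fos_yield, 2), 1.13)
  expect_equal(round_half_up(row$fos_soderberg, 3), 1.023)

  # homogeneity: doubling all stresses halves both FoS
  m1 <- safety_map(make_table(4, vm_stress = 20), p)
  m2 <- safety_map(make_table(4, vm_stress = 40), p)
  expect_equal(m2$fos_yield, m1$fos_yield / 2, tolerance = 1e-12)
  expect_equal(m2$fos_soderberg, m1$fos_soderberg / 2, tolerance = 1e-12)

  expect_error(safety_map(make_table(0), p), "empty")
})

test_that("both FoS are strictly decreasing in peak stress", {
  p <- fatigue_params(0.1, 85.5, 70)
  grid <- seq(1, 200, length.out = 100)
  m <- safety_map(make_table(100, vm_stress = 1), p)
  m <- safety_map(transform(make_table(100), vm_stress = grid), p)
  expect_true(all(diff(m$fos_yield) < 0))
  expect_true(all(diff(m$fos_soderberg) < 0))
})

test_that("at R = 1 the fatigue FoS degenerates to the yield FoS", {
  p <- fatigue_params(1, 85.5, 70)
  grid <- seq(5, 150, length.out = 100)
  m <- safety_map(transform(make_table(100), vm_stress = grid), p)
  expect_equal(m$fos_soderberg, m$fos_yield, tolerance = 1e-12)
})

test_that("unsafe classification agrees with the Soderberg line", {
  p <- fatigue_params(0.1, 85.5, 70)
  grid <- expand.grid(sm = seq(0, 120, length.out = 40),
                      sa = seq(0, 100, length.out = 40))
  fos <- soderberg_fos(grid$sa, grid$sm, p)
  above_line <- grid$sa / 70 + grid$sm / 85.5 > 1
  expect_identical(fos < 1, above_line)
})

test_that("unsafe fraction counts elements or weighs volume", {
  p <- fatigue_params(0.1, 85.5, 70)
  safe <- safety_map(make_table(4, vm_stress = 10), p)
  expect_equal(unsafe_fraction(safe), 0)
  bad <- safety_map(make_table(4, vm_stress = 200), p)
  expect_equal(unsafe_fraction(bad), 1)

  mix <- make_table(4)
  mix$vm_stress <- c(200, 10, 10, 10)
  m <- safety_map(mix, p)
  expect_equal(unsafe_fraction(m, "count"), 0.25)
  mix$volume <- c(1, 1, 1, 7)
  m2 <- safety_map(mix, p)
  expect_equal(unsafe_fraction(m2, "volume"), 0.1)
})

test_that("minimum FoS reporting skips unstressed elements and breaks ties by id", {
  p <- fatigue_params(0.1, 85.5, 70)
  tab <- make_table(4)
  tab$vm_stress <- c(0, 50, 80, 80)
  m <- safety_map(tab, p)
  mf <- min_fos(m)
  expect_equal(mf$fos_yield, 85.5 / 80)
  expect_equal(mf$fos_yield_element, 3L)
  expect_true(is.finite(mf$fos_soderberg))
})
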