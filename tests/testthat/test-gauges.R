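test_that("count differences convert to microstrain at the bridge sensitivity", {
  expect_equal(counts_to_microstrain(1234, 1234, 545.4), 0)
  expect_equal(counts_to_microstrain(5454, 0, 545.4), 10)
  expect_equal(counts_to_microstrain(0, 5454, 545.4), -10)
  expect_error(counts_to_microstrain(1, 0, 0), "sensitivity")
})

test_that("rosette reduction handles degenerate states", {
  z <- rosette_principal(0, 0, 0)
  expect_equal(unname(z$principal_strains), c(0, 0))
  eq <- rosette_principal(50, 50, 50)  # equibiaxial: Mohr radius 0
  expect_equal(unname(eq$principal_strains), c(50, 50))
})

test_that("rosette reduction matches the hand-worked and oracle values", {
  s <- rosette_principal(100, 50, 0)
  expect_equal(unname(s$principal_strains), c(100, 0), tolerance = 1e-12)
  expect_equal(s$principal_angle_deg, 0, tolerance = 1e-9)

  # brute-force Mohr-circle rotation oracle over random plane states
  set.seed(42)
  for (i in 1:25) {
    ex <- stats::rnorm(1, sd = 200); ey <- stats::rnorm(1, sd = 200)
    gxy <- stats::rnorm(1, sd = 200)
    ch <- rosette_channels(ex, ey, gxy)
    red <- rosette_principal(ch[1], ch[2], ch[3])
    oracle <- mohr_oracle(ex, ey, gxy)
    expect_equal(unname(red$principal_strains), unname(oracle),
                 tolerance = 1e-6)
  }
})

test_that("first strain invariant and A/C exchange symmetry hold", {
  set.seed(7)
  for (i in 1:20) {
    e <- stats::rnorm(3, sd = 500)
    r1 <- rosette_principal(e[1], e[2], e[3])
    expect_equal(sum(r1$principal_strains), e[1] + e[3], tolerance = 1e-9)
    r2 <- rosette_principal(e[3], e[2], e[1])  # mirrored rosette
    expect_equal(r1$principal_strains, r2$principal_strains,
                 tolerance = 1e-9)
    expect_true(r1$principal_strains[1] >= r1$principal_strains[2])
  }
})

test_that("forward projection then reduction round-trips the state", {
  set.seed(99)
  for (i in 1:20) {
    ex <- stats::rnorm(1, sd = 300); ey <- stats::rnorm(1, sd = 300)
    gxy <- stats::rnorm(1, sd = 300)
    ch <- rosette_channels(ex, ey, gxy)
    red <- rosette_principal(ch[1], ch[2], ch[3])
    tens <- eigen(matrix(c(ex, gxy / 2, gxy / 2, ey), 2))$values
    expect_equal(unname(red$principal_strains), sort(tens, decreasing = TRUE),
                 tolerance = 1e-9 * max(1, abs(tens)))
  }
})

test_that("plane-stress von Mises follows the closed forms", {
  expect_equal(surface_vm_stress(c(0, 0), 16700, 0.3), 0)
  # uniaxial stress state: e2 = -nu e1 gives vm = E e1 exactly
  e1 <- 150
  vm <- surface_vm_stress(c(e1, -0.3 * e1), 16700, 0.3)
  expect_equal(vm, 16700 * e1 * 1e-6, tolerance = 1e-12)
  # hand evaluation at (100, -30) microstrain
  vm2 <- surface_vm_stress(c(100, -30), 16700, 0.3)
  expect_equal(vm2, 1.67, tolerance = 1e-3)
  # homogeneity of degree 1
  expect_equal(surface_vm_stress(c(200, -60), 16700, 0.3), 2 * vm2,
               tolerance = 1e-12)
  expect_error(surface_vm_stress(c(1, 1), 16700, 0.5), "nu")
  expect_error(surface_vm_stress(c(1, 1), 0, 0.3), "E")
})

test_that("point stress ratios flag unshielded sites", {
  expect_equal(stress_ratio(5, 5)$ratio, 1)
  expect_equal(stress_ratio(0, 5)$ratio, 0)
  r <- stress_ratio(1.4, 1.0)
  expect_equal(r$ratio, 1.4)
  expect_false(r$shielded)  # ratio > 1: more stress than intact, no shielding
  expect_error(stress_ratio(1, 0), "undefined")
})

test_that("repeat averaging is channel-wise and guards mixed sites", {
  one <- data.frame(site = "L1", load_step_n = 1200,
                    eA_ue = 10, eB_ue = 5, eC_ue = -3)
  out1 <- average_repeats(one)
  expect_equal(out1[, c("eA_ue", "eB_ue", "eC_ue")],
               one[, c("eA_ue", "eB_ue", "eC_ue")])
  expect_equal(out1$repeats, 1L)

  five <- one[rep(1, 5), ]
  out5 <- average_repeats(five)
  expect_equal(out5$eA_ue, 10)
  expect_equal(out5$repeats, 5L)

  seq5 <- transform(five, eA_ue = 1:5)
  expect_equal(average_repeats(seq5)$eA_ue, 3)
  expect_equal(average_repeats(seq5, fun = "median")$eA_ue, 3)

  mixed <- rbind(one, transform(one, site = "L2"))
  expect_error(average_repeats(mixed), "mixed sites")
})
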