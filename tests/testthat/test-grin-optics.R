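test_that("lens length follows Z = 2*pi*P/sqrt(A)", {
  expect_equal(lens_length(0.261, 0.299), 5.485, tolerance = 1e-3)
  expect_lt(abs(lens_length(0.261, 0.299) - 5.49) / 5.49, 0.001)
  expect_equal(lens_length(0.5, pi), 1.0)
  expect_lt(abs(lens_length(0.259, 0.311) - 5.236) / 5.236, 0.001)
  expect_error(lens_length(-0.1, 0.3), "positive")
  expect_error(lens_length(0.3, 0), "positive")
})

test_that("back working distance matches the closed form and its limits", {
  expect_equal(round(back_working_distance(standard_lens())), 16)
  # half-pitch relay in a uniform medium images the object onto itself
  relay <- grin_lens_spec(0.5, pi, n_front = 1, n_back = 1,
                          front_wd_mm = 0.3, na_mo = 0.4)
  expect_equal(back_working_distance(relay), -0.3, tolerance = 1e-12)
  # collimated output has no finite conjugate
  p <- 0.24
  l1_afocal <- 1.328 / (1.643 * 0.299 * tan(2 * pi * p))
  afocal <- grin_lens_spec(p, 0.299, front_wd_mm = l1_afocal)
  expect_error(back_working_distance(afocal), "afocal")
})

test_that("back working distance agrees with ABCD ray propagation", {
  set.seed(42)
  n_ok <- 0
  while (n_ok < 100) {
    sp <- grin_lens_spec(pitch = runif(1, 0.05, 0.95),
                         sqrt_a = runif(1, 0.2, 0.5),
                         n0_axial = runif(1, 1.4, 1.8),
                         front_wd_mm = runif(1, 0, 0.5),
                         n_front = runif(1, 1, 1.5), n_back = 1,
                         na_mo = 0.4)
    tm <- matriex:::bwd_terms(sp$n0_axial, sp$sqrt_a, sp$length_mm,
                              sp$front_wd_mm, sp$n_front, sp$n_back)
    if (abs(tm$den) < 1e-3) next    # skip near-afocal configurations
    n_ok <- n_ok + 1
    expect_equal(back_working_distance(sp),
                 abcd_back_wd(sp$n0_axial, sp$sqrt_a, sp$length_mm,
                              sp$front_wd_mm, sp$n_front, sp$n_back),
                 tolerance = 1e-6)
  }
})

test_that("compound NA follows the small-angle magnification law", {
  expect_equal(na_compound(0.055, 0.1675), 0.4367, tolerance = 1e-4)
  expect_equal(na_compound(0.1, 0.1675), 0.794, tolerance = 1e-3)
  expect_equal(na_compound(0.1, 1.33), 0.1)
  # linear in NA_DO
  expect_equal(na_compound(0.08, 0.1675), 0.08 / 0.055 * na_compound(0.055, 0.1675))
  expect_error(na_compound(1.2, 0.1675), "0, 1")
})

test_that("effective NA is capped by both apertures", {
  expect_equal(na_effective(0.794, 0.483), 0.483)
  expect_equal(na_effective(0.4367, 0.483), 0.4367)
  expect_equal(na_effective(0.3, 0.3), 0.3)
  for (x in c(0.1, 0.4, 0.9)) for (y in c(0.2, 0.5)) {
    expect_lte(na_effective(x, y), x)
    expect_lte(na_effective(x, y), y)
  }
})

test_that("lateral magnification matches the Lagrange relation and ray trace", {
  expect_equal(lateral_magnification(0.1675, 1.328, 1.0), 7.93,
               tolerance = 1e-3)
  expect_equal(lateral_magnification(1, 1, 1), 1)
  # independent ray trace of the standard lens; the manufacturer M_a is a
  # rounded catalogue value, so agreement is at the percent level
  sp <- standard_lens()
  ml_trace <- abcd_lateral_mag(sp$n0_axial, sp$sqrt_a, sp$length_mm,
                               sp$front_wd_mm, sp$n_front, sp$n_back)
  expect_equal(lateral_magnification(sp$angular_mag, sp$n_front, sp$n_back),
               ml_trace, tolerance = 0.02)
})

test_that("lens spec validation enforces the catalogue relations", {
  expect_error(grin_lens_spec(1.2, 0.3), "pitch")
  expect_error(grin_lens_spec(0.26, 0.3, length_mm = 6), "0.2%")
  expect_error(grin_lens_spec(0.26, 0.3, na_mo = 1.4), "n_front")
  expect_error(grin_lens_spec(0.26, 0.3, n0_axial = 0.9), ">= 1")
  # printed rounded length is accepted
  expect_silent(grin_lens_spec(0.261, 0.299, length_mm = 5.49))
})

test_that("optical coupling ties the half-angles and caps NA_eff", {
  cp <- optical_coupling(dry_objective_spec(2, 0.055, "Mitutoyo x2"),
                         standard_lens())
  expect_equal(cp$theta0, cp$ma * cp$theta1)
  expect_lte(cp$na_eff, cp$na_comp)
  expect_lte(cp$na_eff, cp$na_mo)
  expect_equal(cp$na_eff, 0.4367, tolerance = 1e-4)
  cp4 <- optical_coupling(dry_objective_spec(4, 0.1), standard_lens())
  expect_equal(cp4$na_eff, 0.483)
})
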