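test_that("target zone scales inversely with DO magnification", {
  expect_equal(target_zone_diameter(2), 12)
  expect_equal(target_zone_diameter(2.5), 9.6)
  expect_equal(target_zone_diameter(4), 6)
  expect_equal(target_zone_diameter(5), 4.8)
  expect_equal(target_zone_diameter(1, 17), 17)
})

test_that("pixel sizes follow the zoomed field and MO magnification", {
  g <- scan_geometry(base_field_mm = 6, zoom = 1.4, npix = 1200,
                     lateral_mag_mo = 7.93)
  px <- pixel_size(g)
  expect_equal(px[["do_plane_um"]], 6000 / 1.4 / 1200, tolerance = 1e-12)
  expect_equal(round(px[["do_plane_um"]]), 4)
  expect_equal(px[["specimen_um"]], px[["do_plane_um"]] / 7.93)
  expect_equal(px[["specimen_um"]], 0.45, tolerance = 1e-2)
  # zoom 1 with npix equal to the field in um gives exactly 1 um pixels
  g1 <- scan_geometry(base_field_mm = 1.2, zoom = 1, npix = 1200,
                      lateral_mag_mo = 1)
  expect_equal(unname(pixel_size(g1)), c(1, 1))
})

test_that("per-FOV power divides the measured total", {
  expect_equal(per_fov_power(112, 3), 112 / 3)
  expect_equal(round(per_fov_power(112, 3)), 37)
})

test_that("PSF lookup returns the measured bead FWHMs", {
  expect_equal(unname(psf_fwhm_lookup(4)), c(1.1, 37))
  expect_equal(unname(psf_fwhm_lookup(2, off_axis = TRUE)), c(1.8, 54))
  expect_equal(unname(psf_fwhm_lookup(dry_objective_spec(2.5, 0.08))),
               c(1.4, 42))
  expect_error(psf_fwhm_lookup(10), "supported models")
  for (m in c(2, 2.5, 4, 5))
    expect_lte(psf_fwhm_lookup(m)[["lateral_um"]],
               psf_fwhm_lookup(m, off_axis = TRUE)[["lateral_um"]])
})
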