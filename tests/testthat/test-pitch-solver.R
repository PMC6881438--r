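test_that("pitch solver inverts the forward conjugation exactly", {
  std <- standard_lens()
  H <- 21.4
  d <- forward_target_depth(std, H)
  sol <- solve_pitch_for_depth(d, H, std)
  expect_equal(sol$pitch, std$pitch, tolerance = 1e-6)
  expect_lt(sol$conjugation_residual_mm, 1e-6)
  expect_gt(sol$protrusion_mm, 0)
  # determinism
  sol2 <- solve_pitch_for_depth(d, H, std)
  expect_identical(sol$pitch, sol2$pitch)
})

test_that("round trip holds across the supported depth range", {
  std <- standard_lens()
  H <- 21.4
  for (d in seq(0.15, 1.5, length.out = 7)) {
    sol <- solve_pitch_for_depth(d, H, std)
    expect_equal(forward_target_depth(sol, H), d, tolerance = 1e-6)
  }
})

test_that("required conjugation length grows monotonically with depth", {
  std <- standard_lens()
  curve <- pitch_depth_curve(seq(0.15, 1.5, length.out = 25), 21.4, std)
  expect_true(all(diff(curve$conjugation_length_mm) > 0))
  # on this branch a deeper target needs a smaller pitch
  expect_true(all(diff(curve$pitch) < 0))
  expect_true(all(curve$protrusion_mm > 0))
})

test_that("infeasible designs are rejected with the violated constraint", {
  std <- standard_lens()
  expect_error(solve_pitch_for_depth(0.05, 21.4, std), "front working")
  # a low assembly height puts the required conjugation length below the
  # reachable branch: no root anywhere in the bracket
  expect_error(solve_pitch_for_depth(1, 5, std), "conjugation")
  # a deep target under a low assembly makes the lens fully embedded
  expect_error(solve_pitch_for_depth(6, 16, std), "outside the brain")
})

test_that("assembly design verifies per-MO conjugation residuals", {
  std <- standard_lens()
  H <- 21.4
  d_std <- forward_target_depth(std, H)
  lng <- long_lens()
  d_lng <- forward_target_depth(lng, H)
  des <- assembly_design(
    dry_objective_spec(4, 0.1),
    list(list(spec = std, lateral_offset_mm = c(-1, -0.8),
              target_depth_mm = d_std, region = "V1"),
         list(spec = std, lateral_offset_mm = c(1, -0.8),
              target_depth_mm = d_std, region = "M1"),
         list(spec = lng, lateral_offset_mm = c(0, 1),
              target_depth_mm = d_lng, region = "CA1")),
    conjugate_height_mm = H)
  expect_s3_class(des, "assembly_design")
  expect_true(all(vapply(des$mo_entries,
                         function(e) e$conjugation_residual_mm,
                         numeric(1)) <= 1e-3))
  # the long-coupling lens reaches deeper than the standard one
  expect_gt(d_lng, d_std)
  expect_error(
    assembly_design(dry_objective_spec(4, 0.1),
                    list(list(spec = std, lateral_offset_mm = 0,
                              target_depth_mm = d_std + 0.5)),
                    conjugate_height_mm = H),
    "conjugation condition")
})
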