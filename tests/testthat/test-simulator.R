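test_that("layouts derived from an assembly keep disks disjoint and inside", {
  std <- standard_lens()
  H <- 21.4
  d <- forward_target_depth(std, H)
  geom <- scan_geometry(npix = 600, lateral_mag_mo = 7.93)
  des <- assembly_design(
    dry_objective_spec(4, 0.1),
    list(list(spec = std, lateral_offset_mm = c(-1, -0.8), target_depth_mm = d,
              region = "V1"),
         list(spec = std, lateral_offset_mm = c(1, -0.8), target_depth_mm = d,
              region = "M1"),
         list(spec = std, lateral_offset_mm = c(0, 1), target_depth_mm = d,
              region = "CA1")),
    conjugate_height_mm = H)
  lay <- build_layout(des, geom)
  expect_equal(nrow(lay$fovs), 3)
  px <- pixel_size(geom)
  expect_equal(lay$fovs$radius_px,
               rep((200 / 2) / px[["specimen_um"]], 3))
  # single on-axis MO sits at the frame center
  one <- build_layout(assembly_design(
    dry_objective_spec(4, 0.1),
    list(list(spec = std, lateral_offset_mm = 0, target_depth_mm = d)),
    conjugate_height_mm = H), geom)
  expect_equal(one$fovs$cx, (600 + 1) / 2)
  expect_equal(one$fovs$cy, (600 + 1) / 2)
  # two MOs closer than one FOV diameter collide
  expect_error(build_layout(assembly_design(
    dry_objective_spec(4, 0.1),
    list(list(spec = std, lateral_offset_mm = c(0, 0), target_depth_mm = d,
              region = "a"),
         list(spec = std, lateral_offset_mm = c(0.05, 0), target_depth_mm = d,
              region = "b")),
    conjugate_height_mm = H), geom), "overlap")
  # disks must stay inside the frame
  expect_error(build_layout(assembly_design(
    dry_objective_spec(4, 0.1),
    list(list(spec = std, lateral_offset_mm = c(2.2, 0), target_depth_mm = d)),
    conjugate_height_mm = H), geom), "outside")
})

test_that("event-free traces reduce to the latent fluctuation", {
  p <- quiet_params(n_cells = 3)
  gt <- synth_traces(p, duration_s = 10, rate_hz = 10)
  expect_true(all(gt$traces == 0))   # rate 0, driver_amp 0
  expect_equal(vapply(gt$events, nrow, integer(1)),
               setNames(rep(0L, 3), gt$cells$cell))
})

test_that("generation is deterministic under a fixed seed", {
  p <- activity_params(state = "awake", n_cells_per_region = 3, seed = 11,
                       motion_sd_px = 1)
  a <- synth_traces(p, 10, 10)
  b <- synth_traces(p, 10, 10)
  expect_identical(a$traces, b$traces)
  expect_identical(a$events, b$events)
  expect_identical(a$shifts, b$shifts)
  p2 <- activity_params(state = "awake", n_cells_per_region = 3, seed = 12,
                        motion_sd_px = 1)
  expect_false(identical(synth_traces(p2, 10, 10)$traces, a$traces))
})

test_that("sampled amplitudes follow the configured log-normal law", {
  set.seed(derive_seed(2024, "amplitudes"))
  a <- sample_event_amplitudes(10000, -0.46, 0.14)
  ks <- ks.test(a, function(q) pnorm(log10(q), -0.46, 0.14))
  expect_gt(ks$p.value, 0.01)
  # empirical exponents converge to the configured values within 2 SE
  l <- log10(a)
  expect_lt(abs(mean(l) - (-0.46)), 2 * 0.14 / sqrt(10000))
  expect_lt(abs(sd(l) - 0.14), 2 * 0.14 / sqrt(2 * 10000))
})

test_that("shared driver weight w yields pairwise correlation w^2", {
  w <- 0.7
  p <- activity_params(regions = data.frame(region = "V1", n_cells = 2,
                                            event_rate_hz = 0,
                                            amp_log10_mu = -0.46,
                                            amp_log10_sigma = 0.14),
                       driver_weights = matrix(w, 1, 1,
                                               dimnames = list("V1", "d")),
                       driver_amp = 1, driver_tau_s = 0.3, noise_sd = 0,
                       seed = 21)
  gt <- synth_traces(p, duration_s = 300, rate_hz = 10)  # 3000 frames
  r <- cor(gt$traces[, 1], gt$traces[, 2])
  expect_lt(abs(r - w^2), 0.05)
  expect_equal(unname(gt$corr_targets[1, 1]), w^2)
})

test_that("intra-regional correlations exceed inter-regional ones", {
  p <- activity_params(state = "anesthetized", n_cells_per_region = 5,
                       driver_tau_s = 0.5, driver_amp = 1, seed = 31,
                       event_rate_hz = 0)
  gt <- synth_traces(p, duration_s = 120, rate_hz = 10)
  cr <- pairwise_correlations(gt$traces, gt$cells$region)
  intra <- cr$pairs$r[cr$pairs$region_i == cr$pairs$region_j]
  inter <- cr$pairs$r[cr$pairs$region_i != cr$pairs$region_j]
  expect_gt(median(intra), median(inter))
  # cortico-cortical exceeds cortico-hippocampal, as generated
  vm <- cr$pairs$r[cr$pairs$category == "M1-V1"]
  vc <- cr$pairs$r[cr$pairs$category %in% c("CA1-V1", "CA1-M1")]
  expect_gt(median(vm), median(vc))
})

test_that("motion jitter is integer and centred", {
  p <- activity_params(state = "awake", n_cells_per_region = 2,
                       motion_sd_px = 2, seed = 41)
  gt <- synth_traces(p, 60, 10)
  expect_true(all(gt$shifts == round(gt$shifts)))
  expect_lte(abs(mean(gt$shifts[, "dy"])), 0.5)
  expect_lte(abs(mean(gt$shifts[, "dx"])), 0.5)
})

test_that("an empty FOV stays dark without crosstalk", {
  p <- quiet_params(region = c("bright", "dark"), n_cells = 0, seed = 7)
  p$regions$plate_counts <- c(2000, 0)
  p$regions$n_cells <- c(0L, 0L)
  p$bg_counts <- 0
  p$crosstalk_frac <- 0
  # a population is required; give the bright region one silent cell
  p$regions$n_cells <- c(1L, 0L)
  gt <- synth_traces(p, 2, 10)
  lay <- simple_layout(96, c("bright", "dark"))
  mv <- render_movie(gt, lay, p)
  dark <- matriex:::fov_mask(lay, 2)
  expect_equal(max(mask_vals(mv$frames, dark)), 0)
})

test_that("crosstalk leakage is linear in the crosstalk fraction", {
  leak <- vapply(c(0.001, 0.002, 0.004), function(ct) {
    p <- quiet_params(region = c("bright", "dark"), n_cells = 0, seed = 7)
    p$regions$plate_counts <- c(2000, 0)
    p$regions$n_cells <- c(1L, 0L)
    p$bg_counts <- 0
    p$crosstalk_frac <- ct
    gt <- synth_traces(p, 1, 10)
    lay <- simple_layout(96, c("bright", "dark"))
    mv <- render_movie(gt, lay, p)
    mean(mask_vals(mv$frames, matriex:::fov_mask(lay, 2)))
  }, numeric(1))
  expect_equal(leak[2] / leak[1], 2, tolerance = 1e-6)
  expect_equal(leak[3] / leak[1], 4, tolerance = 1e-6)
})

test_that("fixtures round-trip losslessly and are seed-stable on disk", {
  p <- activity_params(state = "anesthetized", n_cells_per_region = 2,
                       seed = 9, motion_sd_px = 1)
  gt <- synth_traces(p, 3, 10)
  lay <- simple_layout(80, p$regions$region)
  mv <- render_movie(gt, lay, p)
  d1 <- make_tempdir()
  d2 <- make_tempdir()
  f1 <- write_fixture(mv, d1)
  mv2 <- read_fixture(d1)
  expect_identical(mv$frames, mv2$frames)
  expect_identical(unname(mv2$truth$shifts), unname(gt$shifts))
  expect_equal(mv2$layout$fovs$cx, lay$fovs$cx)
  # regenerating from the same seed gives byte-identical files
  mvb <- render_movie(synth_traces(p, 3, 10), lay, p)
  f2 <- write_fixture(mvb, d2)
  expect_identical(readBin(f1[["tif"]], "raw", file.size(f1[["tif"]])),
                   readBin(f2[["tif"]], "raw", file.size(f2[["tif"]])))
  expect_identical(readLines(f1[["json"]]), readLines(f2[["json"]]))
  # sidecar validates against the shipped schema
  expect_true(validate_sidecar(jsonlite::read_json(f1[["json"]],
                                                   simplifyVector = TRUE)))
  bad <- jsonlite::read_json(f1[["json"]], simplifyVector = TRUE)
  bad$layout <- NULL
  expect_error(validate_sidecar(bad), "layout")
})
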