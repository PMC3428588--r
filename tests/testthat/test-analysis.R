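test_that("observed probability is the PDF mass inside the ROI", {
  g <- tiny_grid(6, spacing = 2)
  # 4 foci: 3 in one voxel, 1 in another
  tab <- coords_table(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                            c(4, 4, 4)), subdomain_id = 14L)
  pdf <- assemble_pdf4d(tab, g)
  roi1 <- cube_mask(g, 2, 2, 2)      # voxel center (0,0,0)
  expect_equal(observed_probability(pdf, roi1, 14L), 0.75)
  expect_equal(observed_probability(pdf, full_mask(g), 14L), 1)
  expect_equal(observed_probability(pdf, roi_mask(g), 14L), 0)
  # empty channel gives zero
  expect_equal(observed_probability(pdf, full_mask(g), 1L), 0)
  # grid mismatch is a hard error, never a silent misalignment
  expect_error(observed_probability(pdf, full_mask(tiny_grid(6, 1)), 14L),
               "grid")
})

test_that("expected probability is the ROI-to-brain volume ratio", {
  g <- tiny_grid(6, spacing = 2)
  brain <- full_mask(g)                # 216 voxels
  roi <- cube_mask(g, 1:3, 1:3, 1:3)   # 27 voxels
  expect_equal(expected_probability(roi, brain), 27 / 216)
  expect_equal(expected_probability(brain, brain), 1)
  expect_equal(expected_probability(roi_mask(g), brain), 0)
  # ROI voxels outside the brain are excluded, with a warning
  small_brain <- cube_mask(g, 1:2, 1:3, 1:3)  # 18 voxels
  expect_warning(pe <- expected_probability(roi, small_brain), "outside")
  expect_equal(pe, 1)
  expect_error(expected_probability(roi, roi_mask(g)), "zero volume")
})

test_that("the effect-size z matches a hand-computed reference value", {
  # p_o = 0.2, p_e = 0.05, N_b = 1000:
  # z = 0.15 / sqrt((0.2*0.8 + 0.05*0.95)/1000) = 10.41...
  z <- effect_z(0.2, 0.05, 1000)
  expect_lt(abs(z - 10.41), 0.01)
  # symmetry: swapping p_o and p_e flips the sign
  expect_equal(effect_z(0.05, 0.2, 1000), -z, tolerance = 1e-12)
  # z grows with sqrt(N_b)
  expect_equal(effect_z(0.2, 0.05, 4000) / z, 2, tolerance = 1e-12)
})

test_that("degenerate effect-size inputs follow the documented contracts", {
  expect_equal(effect_z(1, 1, 100), 0)      # whole-brain ROI: no effect
  expect_equal(effect_z(0, 0, 100), 0)      # empty ROI: no effect
  expect_equal(effect_z(1, 0, 100), Inf)    # zero variance, positive effect
  expect_equal(effect_z(0, 1, 100), -Inf)
  expect_true(is.na(effect_z(0.2, 0.1, 0)))   # no foci: undefined
  expect_true(is.na(effect_z(0.2, 0.1, NA)))
  expect_error(effect_z(1.2, 0.1, 10))        # probabilities out of range
})

test_that("analyze_roi matches a brute-force dense-array oracle to 1e-12", {
  set.seed(31)
  g <- tiny_grid(6, spacing = 2)
  n <- 120L
  tab <- coords_table(matrix(runif(3 * n, -1.9, 7.9), ncol = 3),
                      subdomain_id = sample(c(3L, 14L, 40L), n,
                                            replace = TRUE))
  pdf <- assemble_pdf4d(tab, g)
  brain <- full_mask(g)
  roi <- cube_mask(g, 2:4, 2:4, 2:4)
  prof <- analyze_roi(pdf, roi, brain)
  # oracle: dense arrays and the formula written out verbatim
  pe <- sum(roi$vox) / sum(brain$vox)
  for (b in c(3L, 14L, 40L)) {
    dense <- pdf_channel_dense(pdf, b)
    po <- sum(dense[roi$vox])
    nb <- pdf$n_foci[b]
    zo <- (po - pe) / sqrt((po * (1 - po) + pe * (1 - pe)) / nb)
    row <- prof[prof$subdomain_id == b, ]
    expect_equal(row$p_obs, po, tolerance = 1e-12)
    expect_equal(row$p_exp, pe, tolerance = 1e-12)
    expect_equal(row$z, zo, tolerance = 1e-12)
    expect_equal(row$foci_in_roi, as.integer(round(po * nb)))
  }
})

test_that("profiles are ranked by descending z with deterministic tie order", {
  g <- tiny_grid(6, spacing = 2)
  tab <- coords_table(rbind(c(0, 0, 0), c(0, 0, 0), c(6, 6, 6)),
                      subdomain_id = c(14L, 27L, 3L))
  pdf <- assemble_pdf4d(tab, g)
  prof <- analyze_roi(pdf, cube_mask(g, 2, 2, 2), full_mask(g))
  expect_equal(nrow(prof), 51L)
  z <- prof$z
  expect_true(all(diff(z[!is.na(z)]) <= 1e-12))
  # 14 and 27 have identical profiles here: ties break by id
  expect_equal(prof$subdomain_id[1:2], c(14L, 27L))
  expect_equal(attr(prof, "z_threshold"), 3.0)
  expect_equal(attr(prof, "brain_volume_mm3"), mask_volume(full_mask(g)))
})

test_that("growing an ROI into a density-free area can only lower its z", {
  g <- tiny_grid(8, spacing = 2)
  tab <- coords_table(matrix(rep(c(0, 0, 0), 50), ncol = 3, byrow = TRUE),
                      subdomain_id = 14L)
  pdf <- assemble_pdf4d(tab, g)
  brain <- full_mask(g)
  z_small <- analyze_roi(pdf, cube_mask(g, 2, 2, 2), brain)
  z_big <- analyze_roi(pdf, cube_mask(g, 1:4, 1:4, 1:4), brain)
  zs <- z_small$z[z_small$subdomain_id == 14]
  zb <- z_big$z[z_big$subdomain_id == 14]
  # p_o stays 1 but p_e grows: the larger ROI is less specific
  expect_lt(zb, zs)
  # an ROI with no density never yields a significantly positive z
  far <- analyze_roi(pdf, cube_mask(g, 7:8, 7:8, 7:8), brain)
  expect_lte(far$z[far$subdomain_id == 14], 0)
  expect_false(any(far$significant))
})

test_that("ROI voxels outside the brain are excluded consistently", {
  g <- tiny_grid(6, spacing = 2)
  brain <- cube_mask(g, 1:4, 1:6, 1:6)
  tab <- coords_table(c(0, 0, 0), subdomain_id = 14L)
  pdf <- assemble_pdf4d(tab, g)
  roi <- cube_mask(g, 3:6, 1:6, 1:6)   # half of it lies outside the brain
  expect_warning(prof <- analyze_roi(pdf, roi, brain), "outside")
  expect_equal(prof$p_exp[1], (2 * 36) / (4 * 36))
})

test_that("profiles export to CSV and JSON and re-import intact", {
  g <- tiny_grid(6, spacing = 2)
  tab <- coords_table(rbind(c(0, 0, 0), c(2, 2, 2)), subdomain_id = 14L)
  pdf <- assemble_pdf4d(tab, g)
  prof <- analyze_roi(pdf, cube_mask(g, 2, 2, 2), full_mask(g))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_profile(prof, csv, "csv")
  back_csv <- utils::read.csv(csv)
  expect_equal(nrow(back_csv), 51L)
  expect_equal(back_csv$z, prof$z, tolerance = 1e-9)
  js <- withr::local_tempfile(fileext = ".json")
  export_profile(prof, js, "json")
  back <- read_profile_json(js)
  expect_equal(back$z, prof$z, tolerance = 1e-12)
  expect_equal(back$subdomain_id, prof$subdomain_id)
  expect_equal(attr(back, "z_threshold"), 3.0)
})
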