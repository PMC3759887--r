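## one centred nucleus plus hand-placed gamma-H2AX blobs
one_nucleus_field <- function(foci_xy = NULL, sigma = 1.3, peak = 12000,
                              planes = 2, peri_xy = NULL, noise = FALSE) {
  f <- make_test_field(h = 256, w = 256)
  f <- stamp_ellipse(f, 128, 128, a = 40, b = 36, level = 15000)
  if (!is.null(foci_xy)) {
    for (i in seq_len(nrow(foci_xy)))
      f <- stamp_blob(f, foci_xy[i, 1], foci_xy[i, 2], sigma, peak,
                      ch = 2, planes = planes)
  }
  if (!is.null(peri_xy)) {
    for (i in seq_len(nrow(peri_xy)))
      f <- stamp_blob(f, peri_xy[i, 1], peri_xy[i, 2], 1.7, 20000,
                      ch = 3, planes = planes)
  }
  f
}

test_that("a single noise-free focus is detected once, on target", {
  f <- one_nucleus_field(foci_xy = cbind(120, 135))
  nuc <- segment_nuclei(f)
  sp <- detect_spots(f, nuc, "gH2AX")
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x - 120), 1)
  expect_lt(abs(sp$y - 135), 1)
  expect_identical(sp$nucleus_id, nuc$table$nucleus_id[1])
})

test_that("foci closer than one diameter merge into a single detection", {
  ## footprints fuse at the detection threshold: counted as ONE spot
  f <- one_nucleus_field(foci_xy = rbind(c(126, 128), c(129, 128)))
  nuc <- segment_nuclei(f)
  sp <- detect_spots(f, nuc, "gH2AX")
  expect_identical(nrow(sp), 1L)
  ## independent oracle: raw supra-threshold footprint is one component
  expect_identical(oracle_component_count(f, ch = 2, thr = 2000), 1L)
})

test_that("merging switches from 2 to 1 within the sum of spot radii", {
  detect_at <- function(sep) {
    f <- one_nucleus_field(foci_xy = rbind(c(128 - sep / 2, 128),
                                           c(128 + sep / 2, 128)))
    detect_spots(f, segment_nuclei(f), "gH2AX")
  }
  expect_identical(nrow(detect_at(12)), 2L)
  seps <- seq(12, 1, by = -0.5)
  counts <- vapply(seps, function(s) nrow(detect_at(s)), integer(1))
  switch_sep <- max(seps[counts == 1])
  expect_true(all(counts[seps < switch_sep] == 1))
  ## analytic oracle for two equal Gaussians under a threshold detector:
  ## footprints fuse no later than where the summed tails hold the midpoint
  ## at threshold, i.e. at s with s^2 = 4 r1^2 + 8 sigma_c^2 ln 2, where r1
  ## is the single-spot footprint radius and sigma_c the effective
  ## (spot + band-pass) width; and never before the footprints touch (2 r1)
  wide <- one_nucleus_field(foci_xy = cbind(110, 128))
  r1 <- detect_spots(wide, segment_nuclei(wide), "gH2AX")$diameter_px / 2
  sigma_c <- sqrt(1.3^2 + capture_settings()$dog_sigma_px^2)
  s_upper <- sqrt(4 * r1^2 + 8 * sigma_c^2 * log(2))
  expect_lte(switch_sep, s_upper + 0.5)   # half-step sweep granularity
  expect_gte(switch_sep, 2 * r1 - 0.5)
})

test_that("blank channels and spots outside nuclei give no records", {
  f <- one_nucleus_field()
  nuc <- segment_nuclei(f)
  expect_identical(nrow(detect_spots(f, nuc, "gH2AX")), 0L)
  ## a focus far from any nucleus is discarded
  f2 <- stamp_blob(one_nucleus_field(), 20, 20, 1.3, 12000, ch = 2)
  expect_identical(nrow(detect_spots(f2, segment_nuclei(f2), "gH2AX")), 0L)
  expect_error(detect_spots(f, nuc, "CENPF"), "arg")
})

test_that("spots spanning adjacent planes are merged; distinct spots are not", {
  ## same xy on planes 2 and 3 -> one spot seen twice
  f <- one_nucleus_field(foci_xy = cbind(128, 128), planes = c(2, 3))
  sp <- detect_spots(f, segment_nuclei(f), "gH2AX")
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$n_planes, 2L)
  ## two far-apart spots on adjacent planes stay separate
  f2 <- one_nucleus_field()
  f2 <- stamp_blob(f2, 110, 128, 1.3, 12000, ch = 2, planes = 2)
  f2 <- stamp_blob(f2, 146, 128, 1.3, 12000, ch = 2, planes = 3)
  sp2 <- detect_spots(f2, segment_nuclei(f2), "gH2AX")
  expect_identical(nrow(sp2), 2L)
})

test_that("the diameter gate accepts small spots and rejects large ones", {
  s <- capture_settings()  # 280%
  expect_true(max_diameter_filter(data.frame(diameter_px = 5), s,
                                  reference_diameter_px = 2))
  expect_false(max_diameter_filter(data.frame(diameter_px = 5.7), s,
                                   reference_diameter_px = 2))
  ## boundary inclusive at 100%
  s100 <- capture_settings(spot_diameter_pct = 100)
  expect_true(max_diameter_filter(data.frame(diameter_px = 2), s100,
                                  reference_diameter_px = 2))
  expect_error(max_diameter_filter(data.frame(diameter_px = 2), s, -1),
               "positive")
})

test_that("brightest_focus_intensity is the max over foci, 0 when none", {
  foci <- data.frame(intensity_max = c(10, 40, 25))
  expect_identical(brightest_focus_intensity(foci), 40)
  expect_identical(brightest_focus_intensity(foci[0, , drop = FALSE]), 0)
  expect_identical(brightest_focus_intensity(NULL), 0)
})

test_that("pericentrin counts match truth for nearly all nuclei at default noise", {
  cfg <- generator_config(cells_per_dose = 150, cells_per_field = 80,
                          doses_Gy = 0, s_fraction = 0, m_fraction = 0,
                          seed = 202)
  s <- generate_sample(cfg, 0)
  scored <- score_sample(s$fields, sample_id = "peri", dose_Gy = 0,
                         minimum_nuclei = 1)
  m <- match_cells_to_truth(scored, s$truth)
  expect_gte(nrow(m), 145)
  agree <- mean(m$pericentrin_count == m$true_pericentrin_count)
  expect_gte(agree, 0.99)
  ## every record satisfies the intensity ordering invariant
  f <- s$fields[[1]]
  nuc <- segment_nuclei(f, capture_settings(points_scale = cfg$points_scale))
  for (chn in c("gH2AX", "pericentrin")) {
    sp <- detect_spots(f, nuc, chn,
                       capture_settings(points_scale = cfg$points_scale))
    expect_true(all(sp$intensity_min <= sp$intensity_max))
  }
})
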