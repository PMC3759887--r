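test_that("classify_area partitions (0, Inf) with the documented boundaries", {
  g <- area_gates()
  expect_identical(classify_area(40, g), "debris")
  expect_identical(classify_area(50, g), "G1")       # debris gate -> G1
  expect_identical(classify_area(100, g), "G1")
  expect_identical(classify_area(130, g), "G2")      # G1/G2 gate -> G2
  expect_identical(classify_area(162.7, g), "G2")
  expect_identical(classify_area(250, g), "G2")      # upper gate inclusive
  expect_identical(classify_area(250.0001, g), "overlap_or_polyploid")
  ## total partition over a dense grid
  areas <- seq(0.5, 400, by = 0.25)
  cls <- classify_area(areas, g)
  expect_true(all(cls %in% c("debris", "G1", "G2", "overlap_or_polyploid")))
  expect_identical(classify_area(areas, g), cls)  # deterministic
  expect_error(classify_area(0, g), "positive")
  expect_error(classify_area(-3, g), "positive")
})

test_that("classify_cell combines pericentrin, area and foci into validity", {
  settings <- capture_settings()
  g <- area_gates()
  nuc <- list(nucleus_id = "F01_N001", area_points = 100)
  foci <- data.frame(nucleus_id = rep("F01_N001", 3),
                     intensity_max = c(10, 20, 30))
  peri <- data.frame(nucleus_id = "F01_N001", integrated_intensity = 5e5)
  cc <- classify_cell(nuc, foci, peri, g, settings)
  expect_true(cc$valid)
  expect_identical(cc$area_class, "G1")
  expect_identical(cc$class_group, "p1_f3")
  expect_identical(cc$brightest_focus_intensity, 30)

  ## oversized object with two pericentrin signals: rejected by area
  nuc2 <- list(nucleus_id = "F01_N002", area_points = 300)
  peri2 <- data.frame(nucleus_id = rep("F01_N002", 2),
                      integrated_intensity = c(4e5, 4e5))
  cc2 <- classify_cell(nuc2, NULL, peri2, g, settings)
  expect_false(cc2$valid)
  expect_identical(cc2$area_class, "overlap_or_polyploid")

  ## >= 3 pericentrin signals: presumed touching nuclei, invalid
  peri3 <- data.frame(nucleus_id = rep("F01_N001", 3),
                      integrated_intensity = rep(3e5, 3))
  expect_false(classify_cell(nuc, NULL, peri3, g, settings)$valid)
  ## zero pericentrin: marker not captured, invalid
  expect_false(classify_cell(nuc, foci, NULL, g, settings)$valid)

  ## raw counts cap at the top focus class
  foci14 <- data.frame(nucleus_id = rep("F01_N001", 14),
                       intensity_max = seq_len(14))
  cc14 <- classify_cell(nuc, foci14, peri, g, settings)
  expect_identical(cc14$foci_count_raw, 14L)
  expect_identical(cc14$foci_count, 10L)
  expect_identical(cc14$class_group, "p1_f10")

  ## S/M patterned cells are never scored
  ccS <- classify_cell(nuc, foci, peri, g, settings,
                       phase_flag = "S_pattern")
  expect_false(ccS$valid)
  expect_true(is.na(ccS$class_group))

  ## records from another nucleus are a hard error
  bad <- data.frame(nucleus_id = "F02_N001", intensity_max = 1)
  expect_error(classify_cell(nuc, bad, peri, g, settings), "different")
})

test_that("pan-nuclear patterns are recognised on rendered cells", {
  ## confusion-matrix oracle on generator-rendered S and M cells
  n_each <- 100
  flags <- matrix(NA_character_, n_each, 2,
                  dimnames = list(NULL, c("S", "M")))
  for (i in seq_len(n_each)) {
    for (ph in c("S", "M")) {
      cfg <- small_config(seed = 3000 + i)
      fld <- render_pattern_cell(ph, cfg)
      sc <- score_field(fld, capture_settings(points_scale =
                                                cfg$points_scale))
      if (nrow(sc$cells) == 1) flags[i, ph] <- sc$cells$phase_flag
    }
  }
  expect_gte(mean(flags[, "S"] == "S_pattern", na.rm = TRUE), 0.95)
  expect_gte(mean(flags[, "M"] == "M_pattern", na.rm = TRUE), 0.95)
  expect_lt(mean(is.na(flags)), 0.02)

  ## a cell with a few discrete foci stays interphase
  f <- make_test_field()
  f <- stamp_ellipse(f, 128, 128, a = 40, b = 36, level = 15000)
  for (x in c(110, 128, 146))
    f <- stamp_blob(f, x, 128, 1.3, 12000, ch = 2, planes = 2)
  f <- stamp_blob(f, 115, 115, 1.7, 20000, ch = 3, planes = 2)
  sc <- score_field(f)
  expect_identical(sc$cells$phase_flag, "interphase_foci")
  expect_identical(sc$cells$foci_count, 3L)

  expect_error(pan_nuclear_flag(integer(0), matrix(0, 2, 2)), "empty")
})

test_that("gate calibration reproduces the labelled-population procedure", {
  cal <- calibrate_area_gates(c(130, 162.7, 250))
  expect_equal(cal$gates$g1_max_points, 130)
  expect_equal(cal$gates$g2_max_points, 250)
  expect_equal(cal$mean_labelled_area, 180.9, tolerance = 1e-6)

  expect_error(calibrate_area_gates(160), "at least 2")
  expect_error(calibrate_area_gates(c(160, 160)), "degenerate")
  expect_error(calibrate_area_gates(c(-1, 200)), "positive")

  ## order-statistics recovery: uniform labelled G2 areas on [130, 250]
  set.seed(606)
  areas <- runif(500, 130, 250)
  cal2 <- calibrate_area_gates(areas)
  expect_lt(abs(cal2$gates$g1_max_points - 130), 3)
  expect_lt(abs(cal2$gates$g2_max_points - 250), 3)
  ## analytic order-statistics oracle: E[min] = 130 + 120/501
  expect_lt(abs(cal2$gates$g1_max_points - (130 + 120 / 501)), 3)
})

test_that("scored G2 ground-truth cells are gated G2 almost always", {
  cfg <- generator_config(cells_per_dose = 150, cells_per_field = 80,
                          g2_fraction = 0.5, s_fraction = 0, m_fraction = 0,
                          doses_Gy = 0, seed = 404)
  s <- generate_sample(cfg, 0)
  scored <- score_sample(s$fields, sample_id = "g2", dose_Gy = 0,
                         minimum_nuclei = 1)
  m <- match_cells_to_truth(scored, s$truth)
  g2 <- m[m$true_phase == "G2", ]
  expect_gt(nrow(g2), 40)
  expect_gte(mean(g2$area_class == "G2"), 0.95)
  ## class groups of valid cells are exhaustive and exclusive
  v <- scored$cells[scored$cells$valid, ]
  expect_true(all(grepl("^p[12]_f([0-9]|10)$", v$class_group)))
})
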