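## minimal classification table builder
cells_df <- function(foci, valid = TRUE, area_class = "G1", peri = 1,
                     brightest = foci * 10, peri_int = 1e5) {
  n <- length(foci)
  data.frame(nucleus_id = sprintf("F01_N%03d", seq_len(n)),
             area_points = ifelse(area_class == "G1", 100, 200),
             area_class = area_class,
             pericentrin_count = as.integer(rep(peri, length.out = n)),
             foci_count_raw = as.integer(foci),
             foci_count = as.integer(pmin(foci, 10)),
             phase_flag = "interphase_foci",
             valid = rep(valid, length.out = n),
             class_group = sprintf("p1_f%d", pmin(foci, 10)),
             brightest_focus_intensity = brightest,
             pericentrin_integrated_intensity = peri_int,
             stringsAsFactors = FALSE)
}

test_that("summarize_sample computes means, SEs and histograms over valid cells", {
  s <- summarize_sample(cells_df(c(1, 2, 3)), minimum_nuclei = 1)
  expect_equal(s$mean_foci, 2)
  expect_equal(s$se_foci, 1 / sqrt(3))
  expect_identical(unname(s$foci_histogram),
                   c(0L, 1L, 1L, 1L, rep(0L, 7)))
  expect_identical(s$n_valid_cells, 3L)

  ## all-invalid sample is a QC error
  expect_error(summarize_sample(cells_df(c(1, 2), valid = FALSE)),
               "no valid cells")
  ## short samples only warn
  expect_warning(summarize_sample(cells_df(c(1, 2, 3)),
                                  minimum_nuclei = 1000),
                 "minimum")

  ## stratified means recombine into the overall mean (conservation)
  cells <- rbind(cells_df(c(1, 1, 2), area_class = "G1"),
                 cells_df(c(4, 6), area_class = "G2"))
  s2 <- summarize_sample(cells, minimum_nuclei = 1)
  g1 <- s2$per_area_class$G1; g2 <- s2$per_area_class$G2
  expect_equal(g1$n_valid_cells + g2$n_valid_cells, s2$n_valid_cells)
  expect_equal((g1$mean_foci * g1$n_valid_cells +
                  g2$mean_foci * g2$n_valid_cells) / s2$n_valid_cells,
               s2$mean_foci)
  expect_gt(g2$mean_foci, g1$mean_foci)
})

test_that("Mann-Whitney test matches the exact permutation oracle on small groups", {
  cases <- list(
    list(x = c(0, 0, 0, 0), y = c(5, 5, 5, 5)),
    list(x = c(1, 3, 5), y = c(2, 4, 6)),
    list(x = c(0, 1, 1, 2, 7), y = c(2, 2)),
    list(x = c(1, 1, 2, 2, 3, 3, 4, 4), y = c(2, 3, 3, 5, 5, 6, 7, 8)),
    list(x = c(2, 2, 2), y = c(2, 2, 2, 2)))
  for (cs in cases) {
    got <- compare_doses(cs$x, cs$y)
    want <- oracle_mann_whitney(cs$x, cs$y)
    expect_equal(got$statistic, want$U, info = paste(cs$x, collapse = ","))
    expect_equal(got$p.value, want$p, info = paste(cs$x, collapse = ","))
  }
  ## the all-zeros vs all-fives case has the minimal U and the minimal
  ## attainable two-sided p = 2 / choose(8, 4)
  r <- compare_doses(c(0, 0, 0, 0), c(5, 5, 5, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 2 / choose(8, 4))
})

test_that("large-sample Mann-Whitney agrees with wilcox.test and detects dose shifts", {
  set.seed(99)
  x <- rpois(60, 1.1); y <- rpois(80, 1.9)
  got <- compare_doses(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)

  ## identical samples compare as indistinguishable
  same <- compare_doses(c(rep(0, 30), rep(2, 30)), c(rep(0, 30), rep(2, 30)))
  expect_gt(same$p.value, 0.9)

  ## generated dose contrast at the configured rates is overwhelming
  cfg <- generator_config(cells_per_dose = 1000, doses_Gy = c(0, 0.1),
                          foci_rate_table = NULL, s_fraction = 0,
                          m_fraction = 0, seed = 17)
  c0 <- simulate_ground_truth(cfg, 0)$true_focus_count
  c1 <- simulate_ground_truth(cfg, 0.1)$true_focus_count
  expect_lt(compare_doses(c0, c1)$p.value, 1e-4)
  expect_error(compare_doses(numeric(0), c1), "non-empty")
})

test_that("intensity_dose_fit recovers exact linear relationships", {
  d <- data.frame(dose_Gy = c(0, 1, 2),
                  mean_brightest_intensity = c(1, 3, 5))
  fit <- intensity_dose_fit(d)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  o <- oracle_ols(d$dose_Gy, d$mean_brightest_intensity)
  expect_equal(fit$slope, o$slope)
  expect_error(intensity_dose_fit(d[1:2, ]), "3 dose points")
})

test_that("Spearman correlation behaves on monotone data and transforms", {
  up <- cells_df(rep(1, 20), peri_int = (1:20)^2)
  up$area_points <- 1:20
  expect_equal(pericentrin_area_correlation(up)$spearman_r, 1)
  down <- up; down$pericentrin_integrated_intensity <- rev(up$area_points)
  expect_equal(pericentrin_area_correlation(down)$spearman_r, -1)
  ## invariance under strictly monotone transforms
  tr <- up; tr$pericentrin_integrated_intensity <-
    exp(tr$pericentrin_integrated_intensity / 100)
  expect_equal(pericentrin_area_correlation(tr)$spearman_r, 1)
  expect_error(pericentrin_area_correlation(up[1:5, ]), "at least")
})

test_that("repeatability is the absolute difference of means", {
  r1 <- list(mean_foci = 1.12); r2 <- list(mean_foci = 1.15)
  expect_equal(repeatability(r1, r2), 0.03)
  expect_equal(repeatability(r1, r1), 0)
})

test_that("manual agreement regression matches the normal-equations oracle", {
  d <- data.frame(manual_mean = c(1, 2, 3), auto_mean = c(1, 2, 3))
  fit <- manual_agreement(d)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  ## small-area stratum agreement line: slope ~1.645, intercept ~0.31
  d2 <- data.frame(manual_mean = c(1, 2, 3),
                   auto_mean = c(1.95, 3.60, 5.24))
  fit2 <- manual_agreement(d2, stratum = "G1")
  o <- oracle_ols(d2$manual_mean, d2$auto_mean)
  expect_equal(fit2$slope, o$slope)
  expect_equal(fit2$slope, 1.645, tolerance = 0.001)
  expect_equal(fit2$intercept, 0.31, tolerance = 0.02)
  expect_gt(fit2$r_squared, 0.99)
  expect_error(manual_agreement(d[1, , drop = FALSE]), "3 paired")
})
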