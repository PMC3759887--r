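## Sample summaries and dose-response statistics.

#' Summarise the focus scoring of one sample
#'
#' Computes, over valid cells only, the mean and standard error of the
#' capped focus count (classes 0..max), the focus-count histogram, and the
#' mean brightest-focus intensity (over cells with at least one detected
#' focus). With `stratify = TRUE` the same summaries are produced for the
#' G1-only and G2-only subsets; restricting the analysis to G1 removes the
#' higher G2 focus background from dose comparisons.
#'
#' The standard error reported is the cell-level SE (sample SD divided by
#' the square root of the number of valid cells); replicate-level
#' variability is available by summarising replicates separately and
#' comparing with [repeatability()].
#'
#' @param cells Classification data.frame from [classify_cells()].
#' @param stratify Add per-area-class summaries?
#' @param sample_id,dose_Gy Identifiers carried into the result.
#' @param minimum_nuclei QC minimum of valid nuclei per sample (default
#'   1000); falling short only raises a warning flag, zero valid cells is
#'   an error.
#' @param max_foci_class Top focus class of the histogram.
#' @return A list of class `sample_result`.
#' @export
summarize_sample <- function(cells, stratify = TRUE, sample_id = "sample",
                             dose_Gy = NA_real_, minimum_nuclei = 1000,
                             max_foci_class = 10) {
  v <- cells[cells$valid, , drop = FALSE]
  if (nrow(v) == 0) {
    stop("no valid cells in sample '", sample_id, "': ",
         nrow(cells), " cells total, ",
         sum(!cells$pericentrin_count %in% 1:2),
         " outside the 1-2 pericentrin window, ",
         sum(!cells$area_class %in% c("G1", "G2")),
         " outside the G1/G2 area gates, ",
         sum(cells$phase_flag != "interphase_foci"), " S/M-patterned")
  }
  one <- function(sub) {
    n <- nrow(sub)
    list(n_valid_cells = n,
         mean_foci = mean(sub$foci_count),
         se_foci = if (n > 1) sd(sub$foci_count) / sqrt(n) else NA_real_,
         foci_histogram = tabulate(sub$foci_count + 1L,
                                   nbins = max_foci_class + 1L),
         mean_brightest_intensity =
           if (any(sub$foci_count_raw > 0))
             mean(sub$brightest_focus_intensity[sub$foci_count_raw > 0])
           else 0)
  }
  res <- c(list(sample_id = sample_id, dose_Gy = dose_Gy), one(v))
  names(res$foci_histogram) <- 0:max_foci_class
  if (stratify) {
    res$per_area_class <- lapply(
      c(G1 = "G1", G2 = "G2"),
      function(cl) one(v[v$area_class == cl, , drop = FALSE]))
  }
  res$qc <- list(
    n_cells_total = nrow(cells),
    n_invalid_pericentrin = sum(!cells$pericentrin_count %in% 1:2),
    n_invalid_area = sum(!cells$area_class %in% c("G1", "G2")),
    n_pattern_flagged = sum(cells$phase_flag != "interphase_foci"),
    minimum_nuclei = minimum_nuclei,
    qc_pass = nrow(v) >= minimum_nuclei)
  if (!res$qc$qc_pass)
    warning("sample '", sample_id, "': only ", nrow(v),
            " valid nuclei (minimum ", minimum_nuclei, ")")
  structure(res, class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("Sample %s (%s Gy): %d valid cells, %.3f +/- %.3f foci/cell\n",
              x$sample_id, format(x$dose_Gy), x$n_valid_cells,
              x$mean_foci, x$se_foci))
  invisible(x)
}

.as_counts <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("valid", "foci_count") %in% names(x)))
      stop("expected a classification data.frame or a numeric vector")
    return(x$foci_count[x$valid])
  }
  as.numeric(x)
}

#' Mann-Whitney comparison of per-cell focus counts between two samples
#'
#' Two-sided Mann-Whitney U test on per-cell focus counts, with ties
#' handled by midranks. For small groups (both sizes at most 8) the exact
#' permutation null of U given the pooled data is enumerated; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. P-values are unadjusted.
#'
#' @param a,b Numeric vectors of per-cell counts, or classification
#'   data.frames (valid cells' capped counts are used).
#' @return List with `statistic` (U of group `a`), `p.value`, `n1`, `n2`
#'   and `method`.
#' @export
compare_doses <- function(a, b) {
  x <- .as_counts(a); y <- .as_counts(b)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pool <- c(x, y)
  rk <- rank(pool)
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= 8) {
    splits <- combn(n1 + n2, n1)
    Rs <- colSums(matrix(rk[splits], nrow = n1))
    Us <- Rs - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U1 - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    N <- n1 + n2
    ties <- table(pool)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = U1, p.value = p, n1 = n1, n2 = n2, method = method)
}

#' Linear fit of mean brightest-focus intensity on dose
#'
#' Ordinary least squares of the per-sample mean brightest-focus intensity
#' on dose. A high coefficient of determination together with a moderate
#' gain in mean counts is the signature of focus widening and merging at
#' higher doses.
#'
#' @param samples List of `sample_result`s (>= 3 dose points), or a
#'   data.frame with columns `dose_Gy` and `mean_brightest_intensity`.
#' @return List with `slope`, `intercept`, `r_squared` and `n`.
#' @export
intensity_dose_fit <- function(samples) {
  if (is.data.frame(samples)) {
    d <- samples
  } else {
    d <- data.frame(
      dose_Gy = vapply(samples, `[[`, numeric(1), "dose_Gy"),
      mean_brightest_intensity =
        vapply(samples, `[[`, numeric(1), "mean_brightest_intensity"))
  }
  if (nrow(d) < 3 || length(unique(d$dose_Gy)) < 3)
    stop("need at least 3 dose points")
  fit <- lm(mean_brightest_intensity ~ dose_Gy, data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = .r_squared(fit, d$mean_brightest_intensity), n = nrow(d))
}

#' Spearman correlation of pericentrin intensity with nuclear area
#'
#' Pericentrin integrated intensity grows with nuclear area through the
#' cell cycle, which is what makes it usable as a G1/G2 discriminator. The
#' correlation is computed on valid cells carrying exactly one pericentrin
#' signal (cells already showing two split centrosome signals are late
#' G2/M and are excluded).
#'
#' @param cells Classification data.frame with
#'   `pericentrin_integrated_intensity`.
#' @param min_n Minimum number of usable cells (default 10).
#' @return List with `spearman_r`, `p_value` and `n`.
#' @export
pericentrin_area_correlation <- function(cells, min_n = 10) {
  sel <- cells$valid & cells$pericentrin_count == 1L &
    is.finite(cells$pericentrin_integrated_intensity)
  d <- cells[sel, , drop = FALSE]
  if (nrow(d) < min_n)
    stop("need at least ", min_n, " valid single-pericentrin cells")
  ct <- suppressWarnings(
    cor.test(d$area_points, d$pericentrin_integrated_intensity,
             method = "spearman", exact = FALSE))
  list(spearman_r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Scoring repeatability between two rounds
#'
#' Absolute difference of the mean focus counts of the same sample scored
#' twice. The pipeline is deterministic given identical settings, so the
#' expected value on identical inputs is exactly 0; the acceptance bound
#' used for instrument-style repeatability is 0.05 foci/cell.
#'
#' @param run1,run2 `sample_result`s of the two scoring rounds.
#' @return `|mean_foci(run1) - mean_foci(run2)|`.
#' @export
repeatability <- function(run1, run2) {
  abs(run1$mean_foci - run2$mean_foci)
}

#' Agreement between automatic and manual focus scoring
#'
#' OLS regression of automatic (possibly area-stratified) per-sample mean
#' focus counts on manually scored means of the same samples. Because a
#' manual scorer does not separate cell-cycle phases while the automatic
#' G2 stratum carries a higher focus background, slopes well above 1 are
#' expected for the large-area stratum.
#'
#' @param pairs Data.frame (or 2-column matrix) with columns `manual_mean`
#'   and `auto_mean`, >= 3 rows.
#' @param stratum Label of the automatic stratum being compared (carried
#'   through to the result).
#' @return List with `slope`, `intercept`, `r_squared`, `n`, `stratum`.
#' @export
manual_agreement <- function(pairs, stratum = "all") {
  d <- as.data.frame(pairs)
  if (ncol(d) >= 2 && !all(c("manual_mean", "auto_mean") %in% names(d)))
    names(d)[1:2] <- c("manual_mean", "auto_mean")
  if (nrow(d) < 3) stop("need at least 3 paired sample means")
  fit <- lm(auto_mean ~ manual_mean, data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = .r_squared(fit, d$auto_mean), n = nrow(d),
       stratum = stratum)
}

.r_squared <- function(fit, y) {
  1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
}
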