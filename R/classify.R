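## Cell-cycle gating and per-nucleus classification.

#' Classify nuclear area into cell-cycle area classes
#'
#' Partitions positive area (points) into `debris` (below the debris gate),
#' `G1`, `G2` and `overlap_or_polyploid` (above the G2 gate, presumed
#' overlapped nuclei or polyploid cells). The partition is total and
#' deterministic; boundary convention: the debris gate value belongs to G1
#' and both the G1/G2 gate and the upper G2 gate belong to G2, because the
#' CENP-F positive calibration cells were observed at both ends of the
#' 130-250 range.
#'
#' @param area_points Positive numeric vector of areas in points.
#' @param gates An [area_gates()].
#' @return Character vector of class labels.
#' @examples
#' classify_area(c(40, 100, 162.7, 300), area_gates())
#' @export
classify_area <- function(area_points, gates = area_gates()) {
  stopifnot(inherits(gates, "area_gates"))
  if (!is.numeric(area_points) || any(!is.finite(area_points)) ||
      any(area_points <= 0))
    stop("area_points must be positive")
  out <- character(length(area_points))
  out[area_points < gates$debris_max_points] <- "debris"
  out[area_points >= gates$debris_max_points &
        area_points < gates$g1_max_points] <- "G1"
  out[area_points >= gates$g1_max_points &
        area_points <= gates$g2_max_points] <- "G2"
  out[area_points > gates$g2_max_points] <- "overlap_or_polyploid"
  out
}

#' Pan-nuclear gamma-H2AX pattern flag
#'
#' S-phase cells show rough, granulated gamma-H2AX staining across most of
#' the nucleus; M-phase cells are uniformly and brightly pan-nuclear.
#' Neither pattern yields countable foci, so both must be flagged before
#' counting. The test computes the fraction of nuclear pixels above the
#' gamma-H2AX threshold (coverage) and the coefficient of variation of the
#' supra-threshold intensities: high coverage with low CV (or high coverage
#' in a cell showing two pericentrin signals) is called `M_pattern`, high
#' coverage with high CV is `S_pattern`, everything else is
#' `interphase_foci`.
#'
#' @param mask_idx Integer indices of the nucleus mask pixels into
#'   `gH2AX_projection` (non-empty).
#' @param gH2AX_projection Maximum-intensity projection of the gamma-H2AX
#'   channel (matrix).
#' @param settings A [capture_settings()].
#' @param pericentrin_count The cell's pericentrin count (supports the
#'   M-phase call; default 0).
#' @return One of `"interphase_foci"`, `"S_pattern"`, `"M_pattern"`.
#' @export
pan_nuclear_flag <- function(mask_idx, gH2AX_projection,
                             settings = capture_settings(),
                             pericentrin_count = 0) {
  if (length(mask_idx) == 0) stop("empty nucleus mask")
  v <- as.numeric(gH2AX_projection[mask_idx])
  thr <- settings$gH2AX_threshold
  coverage <- mean(v > thr)
  sup <- v[v > thr]
  cv <- if (length(sup) >= 2) sd(sup) / mean(sup) else 0
  if (coverage >= settings$m_coverage_min &&
      (cv <= settings$cv_cut || pericentrin_count == 2))
    return("M_pattern")
  if (coverage >= settings$s_coverage_min && cv > settings$cv_cut)
    return("S_pattern")
  "interphase_foci"
}

#' Classify one nucleus
#'
#' Combines the pericentrin count, the capped focus count, the area class
#' and the pan-nuclear phase flag into the cell classification. A cell is
#' `valid` (scorable) iff it carries 1 or 2 pericentrin signals, its area
#' class is G1 or G2, and its gamma-H2AX staining is interphase-like. Zero
#' pericentrin signals mean the marker was not captured; three or more mean
#' the object is presumed to be touching nuclei scored as one - both cases
#' are rejected rather than scored. Valid cells are assigned to the class
#' group `(pericentrin_count, foci_count)`, the full cross product
#' \{1,2\} x \{0..max_foci_class\}.
#'
#' @param nucleus One row of a [segment_nuclei()] table (or any list with
#'   `nucleus_id` and `area_points`).
#' @param foci Focus records of this nucleus (gamma-H2AX), possibly empty.
#' @param pericentrin Pericentrin records of this nucleus, possibly empty.
#' @param gates An [area_gates()].
#' @param settings A [capture_settings()].
#' @param phase_flag Pan-nuclear flag from [pan_nuclear_flag()]; defaults
#'   to interphase.
#' @return One-row data.frame: `nucleus_id`, `area_points`, `area_class`,
#'   `pericentrin_count`, `foci_count_raw`, `foci_count`, `phase_flag`,
#'   `valid`, `class_group`, `brightest_focus_intensity`,
#'   `pericentrin_integrated_intensity`.
#' @export
classify_cell <- function(nucleus, foci = NULL, pericentrin = NULL,
                          gates = area_gates(),
                          settings = capture_settings(),
                          phase_flag = "interphase_foci") {
  id <- nucleus$nucleus_id
  for (tab in list(foci, pericentrin)) {
    if (!is.null(tab) && nrow(tab) &&
        !all(tab$nucleus_id == id))
      stop("focus records belong to a different nucleus")
  }
  pc <- if (is.null(pericentrin)) 0L else nrow(pericentrin)
  raw <- if (is.null(foci)) 0L else nrow(foci)
  capped <- as.integer(min(raw, settings$max_foci_class))
  a_class <- classify_area(nucleus$area_points, gates)
  valid <- (pc %in% c(1L, 2L)) && a_class %in% c("G1", "G2") &&
    phase_flag == "interphase_foci"
  data.frame(
    nucleus_id = id,
    area_points = nucleus$area_points,
    area_class = a_class,
    pericentrin_count = pc,
    foci_count_raw = raw,
    foci_count = capped,
    phase_flag = phase_flag,
    valid = valid,
    class_group = if (valid) sprintf("p%d_f%d", pc, capped) else
      NA_character_,
    brightest_focus_intensity = brightest_focus_intensity(foci),
    pericentrin_integrated_intensity =
      if (pc > 0) sum(pericentrin$integrated_intensity) else 0,
    stringsAsFactors = FALSE)
}

#' Classify every non-boundary nucleus of a field
#'
#' Vectorised driver around [pan_nuclear_flag()] and [classify_cell()].
#' Nuclei flagged as touching the field border are excluded.
#'
#' @param nuclei A `nucleus_set`.
#' @param foci,pericentrin Focus-record tables for the field (after any
#'   diameter filtering).
#' @param gH2AX_projection Maximum-intensity projection of the gamma-H2AX
#'   channel of the same field.
#' @param gates An [area_gates()].
#' @param settings A [capture_settings()].
#' @return Classification data.frame, one row per scored nucleus.
#' @export
classify_cells <- function(nuclei, foci, pericentrin, gH2AX_projection,
                           gates = area_gates(),
                           settings = capture_settings()) {
  tbl <- nuclei$table[!nuclei$table$boundary_touching, , drop = FALSE]
  if (nrow(tbl) == 0) return(.empty_classification())
  idx_all <- which(nuclei$labels > 0)
  masks <- split(idx_all, nuclei$labels[idx_all])
  foci_by <- if (nrow(foci)) split(foci, foci$nucleus_id) else list()
  peri_by <- if (nrow(pericentrin))
    split(pericentrin, pericentrin$nucleus_id) else list()
  out <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    id <- tbl$nucleus_id[i]
    fc <- foci_by[[id]]
    pcr <- peri_by[[id]]
    pc_n <- if (is.null(pcr)) 0L else nrow(pcr)
    flag <- pan_nuclear_flag(masks[[as.character(tbl$label[i])]],
                             gH2AX_projection, settings, pc_n)
    out[[i]] <- classify_cell(tbl[i, ], fc, pcr, gates, settings, flag)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ## hard invariant: no valid cell outside the 1-2 pericentrin window
  stopifnot(all(res$pericentrin_count[res$valid] %in% c(1L, 2L)))
  res
}

.empty_classification <- function() {
  data.frame(nucleus_id = character(), area_points = numeric(),
             area_class = character(), pericentrin_count = integer(),
             foci_count_raw = integer(), foci_count = integer(),
             phase_flag = character(), valid = logical(),
             class_group = character(),
             brightest_focus_intensity = numeric(),
             pericentrin_integrated_intensity = numeric(),
             stringsAsFactors = FALSE)
}

#' Calibrate the G1/G2 area gates from a labelled G2 population
#'
#' Reproduces the gate-calibration procedure: nuclear areas of cells
#' positively labelled for a G2/M marker (CENP-F) are collected, and the
#' G1/G2 gate is placed at their minimum and the upper G2 gate at their
#' maximum. With the observed 130-250 range this yields the default
#' 130/250 gates. The mean labelled area is reported alongside.
#'
#' @param labelled_g2_areas Numeric vector (length >= 2) of areas in
#'   points of marker-positive cells.
#' @param debris_max Debris gate to carry over, points.
#' @return List with `gates` (an [area_gates()]), `mean_labelled_area` and
#'   `n`.
#' @examples
#' calibrate_area_gates(c(130, 162.7, 250))
#' @export
calibrate_area_gates <- function(labelled_g2_areas, debris_max = 50) {
  a <- labelled_g2_areas
  if (length(a) < 2)
    stop("need at least 2 labelled areas to calibrate gates")
  if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0))
    stop("labelled areas must be positive")
  lo <- min(a); hi <- max(a)
  if (lo >= hi) stop("degenerate calibration: all labelled areas equal")
  if (lo <= debris_max)
    stop("labelled areas overlap the debris gate")
  list(gates = area_gates(debris_max_points = debris_max,
                          g1_max_points = lo, g2_max_points = hi),
       mean_labelled_area = mean(a),
       n = length(a))
}
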