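#' Capture and detection settings
#'
#' Bundles every tunable of the scoring stage. Defaults mirror the scanner
#' protocol the pipeline emulates: four focal planes 2.1 um apart for both
#' spot probes, a maximum accepted spot diameter of 280% of the reference
#' spot size, and cell classes built from 1-2 pericentrin signals crossed
#' with 0-10 gamma-H2AX foci. Thresholds are held constant for a whole run
#' (the protocol keeps exposure and camera settings fixed across samples),
#' so no per-field auto-adaptation is performed.
#'
#' @param spot_diameter_pct Maximum accepted spot diameter, as a percentage
#'   of `reference_diameter_px`. Spots with larger threshold footprints are
#'   rejected by [max_diameter_filter()].
#' @param z_planes Number of focal planes per channel.
#' @param z_step_um Spacing between focal planes, micrometres.
#' @param gH2AX_threshold Detection threshold for the gamma-H2AX channel, in
#'   raw intensity units (16-bit scale). Applied to the band-passed image to
#'   delimit spot footprints and to the raw projection for pan-nuclear
#'   coverage.
#' @param pericentrin_threshold Same, for the pericentrin channel.
#' @param pericentrin_dilation_px Dilation margin (pixels) applied to nucleus
#'   masks when assigning pericentrin spots; pericentrin sits at the
#'   centrosome and frequently only overlaps the nuclear border.
#' @param points_scale Linear factor converting nuclear area in pixels to
#'   the scanner's "points" unit (`area_points = area_px * points_scale`).
#' @param max_foci_class Upper focus class; per-cell counts are capped here
#'   (default 10, giving classes 0-10).
#' @param reference_diameter_px Reference spot diameter in pixels for the
#'   `%` diameter gate.
#' @param merge_radius_px Maximum xy distance between per-plane detections
#'   merged into a single spot across adjacent planes.
#' @param min_nucleus_points Minimum nuclear area retained by segmentation
#'   (the debris gate).
#' @param dog_sigma_px,dog_background_sigma_px Standard deviations (pixels)
#'   of the difference-of-Gaussians band-pass used for spot detection.
#' @param s_coverage_min,m_coverage_min,cv_cut Pan-nuclear pattern gates:
#'   minimum supra-threshold coverage for the S and M calls and the
#'   coefficient-of-variation cut separating rough S-phase staining (high
#'   CV) from uniform M-phase staining (low CV).
#' @return A list of class `capture_settings`.
#' @export
capture_settings <- function(spot_diameter_pct = 280,
                             z_planes = 4,
                             z_step_um = 2.1,
                             gH2AX_threshold = 2000,
                             pericentrin_threshold = 2000,
                             pericentrin_dilation_px = 5,
                             points_scale = 0.03,
                             max_foci_class = 10,
                             reference_diameter_px = 4,
                             merge_radius_px = reference_diameter_px,
                             min_nucleus_points = 50,
                             dog_sigma_px = 1.5,
                             dog_background_sigma_px = 5,
                             s_coverage_min = 0.5,
                             m_coverage_min = 0.8,
                             cv_cut = 0.6) {
  s <- list(spot_diameter_pct = spot_diameter_pct, z_planes = z_planes,
            z_step_um = z_step_um, gH2AX_threshold = gH2AX_threshold,
            pericentrin_threshold = pericentrin_threshold,
            pericentrin_dilation_px = pericentrin_dilation_px,
            points_scale = points_scale, max_foci_class = max_foci_class,
            reference_diameter_px = reference_diameter_px,
            merge_radius_px = merge_radius_px,
            min_nucleus_points = min_nucleus_points,
            dog_sigma_px = dog_sigma_px,
            dog_background_sigma_px = dog_background_sigma_px,
            s_coverage_min = s_coverage_min,
            m_coverage_min = m_coverage_min, cv_cut = cv_cut)
  pos <- c("spot_diameter_pct", "z_planes", "z_step_um", "points_scale",
           "max_foci_class", "reference_diameter_px", "min_nucleus_points",
           "dog_sigma_px", "dog_background_sigma_px")
  for (f in pos) {
    if (!is.numeric(s[[f]]) || length(s[[f]]) != 1L || !is.finite(s[[f]]) ||
        s[[f]] <= 0)
      stop("capture_settings: '", f, "' must be a positive number")
  }
  if (s$pericentrin_dilation_px < 0 || s$merge_radius_px < 0)
    stop("capture_settings: dilation and merge radius must be non-negative")
  structure(s, class = "capture_settings")
}

#' Nuclear-area gates for cell-cycle sorting
#'
#' The area gates partition nuclear area (in "points") into four classes:
#' below `debris_max_points` is debris, `[debris_max, g1_max)` is G1,
#' `[g1_max, g2_max]` is G2 and above `g2_max` is presumed overlapped nuclei
#' or polyploid cells. Defaults 50/130/250 come from calibrating the gates
#' on CENP-F positive (hence G2/M) cells, which fell between 130 and 250
#' points; see [calibrate_area_gates()].
#'
#' Boundary convention: 50 is assigned to G1, and both 130 and 250 are
#' assigned to G2, because the calibration population was observed at both
#' extremes of the 130-250 range.
#'
#' @param debris_max_points,g1_max_points,g2_max_points Gate positions in
#'   nuclear-area points; must be strictly increasing.
#' @return A list of class `area_gates`.
#' @export
area_gates <- function(debris_max_points = 50, g1_max_points = 130,
                       g2_max_points = 250) {
  g <- list(debris_max_points = debris_max_points,
            g1_max_points = g1_max_points,
            g2_max_points = g2_max_points)
  if (!all(vapply(g, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1))))
    stop("area_gates: gates must be positive numbers")
  if (!(g$debris_max_points < g$g1_max_points &&
        g$g1_max_points < g$g2_max_points))
    stop("area_gates: gates must satisfy debris_max < g1_max < g2_max")
  structure(g, class = "area_gates")
}

#' Configuration of the synthetic sample generator
#'
#' Describes the population of cells the generator draws and how fields are
#' rendered. The statistical defaults reproduce the measured behaviour of
#' exponentially growing HMEC cultures scored 2 h after X-irradiation:
#' per-cell focus counts are Poisson with dose-dependent means (1.12 at
#' 0 Gy, 4.75 at 0.5 Gy, 5.23 at 1 Gy via `foci_rate_table`), G2 cells carry
#' roughly twice the background focus load of G1 cells, about 16% of cells
#' are in the large-area (G2) group, pericentrin integrated intensity has
#' Spearman correlation 0.4942 with nuclear area, and focus diameter and
#' peak intensity grow linearly with dose (the mechanism behind count
#' saturation at high dose).
#'
#' @param doses_Gy Doses for which samples may be generated.
#' @param cells_per_dose Number of cells per generated sample.
#' @param cells_per_field Nuclei laid out per captured field.
#' @param control_mean_foci Poisson mean focus count of unirradiated G1
#'   cells.
#' @param foci_per_Gy Linear dose coefficient of the focus rate, used for
#'   doses not listed in `foci_rate_table`.
#' @param foci_rate_table `NULL`, or a data.frame with columns `dose_Gy`
#'   and `mean_foci` giving measured mean counts that override the linear
#'   law at those exact doses.
#' @param g2_fraction Fraction of cells in G2.
#' @param s_fraction,m_fraction Fractions of cells rendered with the
#'   pan-nuclear S and M gamma-H2AX patterns instead of discrete foci.
#' @param g2_background_multiplier Multiplier on `control_mean_foci` for G2
#'   cells (default 2: double genome, double background damage signal).
#' @param g1_area_range_points,g2_area_range_points Uniform ranges (points)
#'   from which true nuclear areas are drawn per phase; must not overlap.
#' @param axis_ratio_range Range of the nuclear ellipse minor/major axis
#'   ratio.
#' @param focus_diameter_base_px,focus_diameter_per_Gy Focus FWHM in pixels
#'   at 0 Gy and its linear growth per Gy.
#' @param focus_peak_intensity_base,focus_peak_intensity_per_Gy Focus peak
#'   intensity (16-bit scale) at 0 Gy and its linear growth per Gy.
#' @param focus_peak_cv Coefficient of variation of per-focus peak
#'   intensity.
#' @param focus_sigma_z_um Axial standard deviation of the isotropic 3-D
#'   Gaussian focus model, micrometres.
#' @param focus_min_separation_fwhm Minimum pairwise focus separation, in
#'   FWHM units, enforced when `allow_focus_overlap = FALSE`.
#' @param allow_focus_overlap If `TRUE` (default) foci are placed uniformly
#'   and may overlap, reproducing merge-driven undercounting at high dose;
#'   if `FALSE` the generator enforces the minimum separation.
#' @param pericentrin_area_correlation Target Spearman correlation between
#'   nuclear area and total pericentrin integrated intensity, imposed
#'   through a Gaussian copula on ranks.
#' @param pericentrin_two_prob_g2 Probability that a G2 cell already shows
#'   two separated pericentrin spots (M cells always show two).
#' @param pericentrin_diameter_px Pericentrin spot FWHM in pixels.
#' @param pericentrin_peak_min,pericentrin_peak_max Range of total
#'   pericentrin peak intensity mapped from the copula quantile.
#' @param dapi_level,dapi_cv Mean DAPI intensity of a nucleus and its
#'   between-cell coefficient of variation.
#' @param nucleus_sigma_z_um Axial extent (sd, um) of nuclear staining used
#'   to attenuate off-focus planes.
#' @param background_offset,noise_sd Additive camera baseline and Gaussian
#'   read-noise standard deviation (16-bit scale).
#' @param z_planes,z_step_um Stack geometry (default 4 planes, 2.1 um).
#' @param pixel_size_um Pixel size, micrometres.
#' @param field_width,field_height Field geometry in pixels.
#' @param points_scale Pixels-to-points conversion used to size nuclei.
#' @param touching_fraction Fraction of cells placed as touching pairs with
#'   overlapping masks (0 = strictly disjoint layout).
#' @param s_base_intensity,s_sdlog S-pattern lognormal texture parameters.
#' @param m_level,m_cv M-pattern mean intensity and pixel noise CV.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(doses_Gy = c(0, 0.5, 1),
                             cells_per_dose = 1000,
                             cells_per_field = 80,
                             control_mean_foci = 1.12,
                             foci_per_Gy = 7.26,
                             foci_rate_table = data.frame(
                               dose_Gy = c(0, 0.5, 1),
                               mean_foci = c(1.12, 4.75, 5.23)),
                             g2_fraction = 0.16,
                             s_fraction = 0.05,
                             m_fraction = 0.02,
                             g2_background_multiplier = 2,
                             g1_area_range_points = c(50, 130),
                             g2_area_range_points = c(130, 250),
                             axis_ratio_range = c(0.75, 1),
                             focus_diameter_base_px = 3,
                             focus_diameter_per_Gy = 1,
                             focus_peak_intensity_base = 12000,
                             focus_peak_intensity_per_Gy = 10000,
                             focus_peak_cv = 0.05,
                             focus_sigma_z_um = 1.5,
                             focus_min_separation_fwhm = 2.2,
                             allow_focus_overlap = TRUE,
                             pericentrin_area_correlation = 0.4942,
                             pericentrin_two_prob_g2 = 0.5,
                             pericentrin_diameter_px = 4,
                             pericentrin_peak_min = 8000,
                             pericentrin_peak_max = 45000,
                             dapi_level = 15000,
                             dapi_cv = 0.08,
                             nucleus_sigma_z_um = 3,
                             background_offset = 500,
                             noise_sd = 20,
                             z_planes = 4,
                             z_step_um = 2.1,
                             pixel_size_um = 0.1075,
                             field_width = 1280,
                             field_height = 1024,
                             points_scale = 0.03,
                             touching_fraction = 0,
                             s_base_intensity = 3400,
                             s_sdlog = 0.9,
                             m_level = 9000,
                             m_cv = 0.08,
                             seed = 1L) {
  cfg <- as.list(environment())

  rate_like <- c("control_mean_foci", "foci_per_Gy", "g2_background_multiplier",
                 "focus_diameter_base_px", "focus_diameter_per_Gy",
                 "focus_peak_intensity_base", "focus_peak_intensity_per_Gy",
                 "focus_peak_cv", "focus_sigma_z_um", "noise_sd",
                 "background_offset", "touching_fraction")
  for (f in rate_like) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("generator_config: '", f, "' must be a finite non-negative number")
  }
  if (any(!is.finite(doses_Gy)) || any(doses_Gy < 0))
    stop("generator_config: doses must be finite and non-negative")
  if (!is.null(foci_rate_table)) {
    if (!is.data.frame(foci_rate_table) ||
        !all(c("dose_Gy", "mean_foci") %in% names(foci_rate_table)))
      stop("generator_config: foci_rate_table needs columns dose_Gy, mean_foci")
    if (any(!is.finite(foci_rate_table$mean_foci)) ||
        any(foci_rate_table$mean_foci < 0))
      stop("generator_config: foci_rate_table means must be non-negative")
  }
  for (f in c("g2_fraction", "s_fraction", "m_fraction",
              "pericentrin_two_prob_g2")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("generator_config: '", f, "' must lie in [0, 1]")
  }
  if (g2_fraction + s_fraction + m_fraction > 1)
    stop("generator_config: phase fractions exceed 1")
  if (abs(pericentrin_area_correlation) > 1)
    stop("generator_config: pericentrin_area_correlation must be in [-1, 1]")
  if (diff(g1_area_range_points) <= 0 || diff(g2_area_range_points) <= 0)
    stop("generator_config: area ranges must be non-empty intervals")
  if (g1_area_range_points[2] > g2_area_range_points[1])
    stop("generator_config: G1 and G2 area ranges must not overlap")
  if (cells_per_dose < 0 || cells_per_field < 1)
    stop("generator_config: cell counts must be non-negative")
  if (z_planes < 1 || z_step_um <= 0 || pixel_size_um <= 0 ||
      points_scale <= 0)
    stop("generator_config: stack geometry must be positive")

  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

## Poisson mean focus count for a G1 cell at this dose: measured dose table
## when available, linear law otherwise.
.rate_for_dose <- function(config, dose_Gy) {
  tab <- config$foci_rate_table
  if (!is.null(tab)) {
    hit <- which(abs(tab$dose_Gy - dose_Gy) < 1e-9)
    if (length(hit)) return(tab$mean_foci[hit[1]])
  }
  config$control_mean_foci + config$foci_per_Gy * dose_Gy
}
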