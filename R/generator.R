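## Synthetic z-stack generator.
##
## Cells are drawn at the statistical parameters configured in
## generator_config(), laid out on a jittered grid (non-touching by default),
## and rendered as hard-edged DAPI ellipses plus isotropic 3-D Gaussian spots
## sampled onto the focal planes. All randomness derives from config$seed.

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

.gen_seed <- function(config, dose_Gy) {
  as.integer((abs(config$seed) * 1000003 + round(dose_Gy * 1000)) %%
               .Machine$integer.max)
}

#' Draw the ground-truth cell population for one sample
#'
#' Samples per-cell phase, nuclear area, focus count, pericentrin count and
#' pericentrin intensity without rendering images. This is the statistical
#' core of [generate_sample()], exposed separately so population-level laws
#' (Poisson focus means, the area-intensity copula) can be checked at large
#' n cheaply.
#'
#' Focus counts are Poisson with mean `rate(dose)` for G1 cells and
#' `rate(dose) + (g2_background_multiplier - 1) * control_mean_foci` for G2
#' cells; S and M cells carry a pan-nuclear pattern instead of countable
#' foci. Pericentrin intensity is coupled to nuclear area through a Gaussian
#' copula whose Pearson parameter is chosen so the rank (Spearman)
#' correlation equals `pericentrin_area_correlation`.
#'
#' @param config A [generator_config()].
#' @param dose_Gy Dose of the sample; must be one of `config$doses_Gy`.
#' @param n Number of cells (default `config$cells_per_dose`).
#' @return A data.frame with one row per cell: `cell_id`, `dose_Gy`,
#'   `true_phase`, `true_area_points`, `true_focus_count`,
#'   `true_pericentrin_count`, `true_pericentrin_intensity`, plus the
#'   rendering attributes `axis_ratio`, `angle_rad` and `dapi_level`.
#' @export
simulate_ground_truth <- function(config, dose_Gy,
                                  n = config$cells_per_dose) {
  stopifnot(inherits(config, "generator_config"))
  if (!any(abs(config$doses_Gy - dose_Gy) < 1e-9))
    stop("dose_Gy must be one of config$doses_Gy")
  set.seed(.gen_seed(config, dose_Gy))
  .simulate_truth_body(config, dose_Gy, n)
}

.simulate_truth_body <- function(config, dose_Gy, n) {
  if (n == 0) {
    return(data.frame(cell_id = character(), dose_Gy = numeric(),
                      true_phase = character(), true_area_points = numeric(),
                      true_focus_count = integer(),
                      true_pericentrin_count = integer(),
                      true_pericentrin_intensity = numeric(),
                      axis_ratio = numeric(), angle_rad = numeric(),
                      dapi_level = numeric(), stringsAsFactors = FALSE))
  }
  p_g2 <- config$g2_fraction
  p_s <- config$s_fraction
  p_m <- config$m_fraction
  phase <- sample(c("G1", "G2", "S", "M"), n, replace = TRUE,
                  prob = c(1 - p_g2 - p_s - p_m, p_g2, p_s, p_m))
  big <- phase %in% c("G2", "M")
  area <- numeric(n)
  area[!big] <- runif(sum(!big), config$g1_area_range_points[1],
                      config$g1_area_range_points[2])
  area[big] <- runif(sum(big), config$g2_area_range_points[1],
                     config$g2_area_range_points[2])

  base_rate <- .rate_for_dose(config, dose_Gy)
  rate <- rep(base_rate, n)
  rate[phase == "G2"] <- base_rate +
    (config$g2_background_multiplier - 1) * config$control_mean_foci
  counts <- rpois(n, rate)
  counts[phase %in% c("S", "M")] <- 0L

  peri_n <- rep(1L, n)
  g2i <- which(phase == "G2")
  if (length(g2i))
    peri_n[g2i] <- 1L + rbinom(length(g2i), 1L, config$pericentrin_two_prob_g2)
  peri_n[phase == "M"] <- 2L

  ## Gaussian copula on area ranks; Pearson rho chosen so the Spearman
  ## correlation of the pair equals the configured value.
  rho_s <- config$pericentrin_area_correlation
  rho <- 2 * sin(pi * rho_s / 6)
  z1 <- qnorm(rank(area, ties.method = "random") / (n + 1))
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  q <- pnorm(z2)
  peak_total <- config$pericentrin_peak_min +
    (config$pericentrin_peak_max - config$pericentrin_peak_min) * q
  sigma_p <- config$pericentrin_diameter_px * .FWHM_TO_SIGMA
  peri_int <- peak_total * 2 * pi * sigma_p^2

  data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    dose_Gy = dose_Gy,
    true_phase = phase,
    true_area_points = area,
    true_focus_count = counts,
    true_pericentrin_count = peri_n,
    true_pericentrin_intensity = peri_int,
    axis_ratio = runif(n, config$axis_ratio_range[1],
                       config$axis_ratio_range[2]),
    angle_rad = runif(n, 0, pi),
    dapi_level = config$dapi_level *
      pmax(0.3, 1 + config$dapi_cv * rnorm(n)),
    stringsAsFactors = FALSE)
}

## ---- layout ---------------------------------------------------------------

## Grid layout: slot pitch fits the largest possible nucleus, jitter keeps
## masks strictly inside their slot, so nuclei never touch each other or the
## field border. Touching mode deliberately breaks this for a fraction of
## cells by co-locating pairs in one slot.
.layout_sample <- function(truth, config) {
  n <- nrow(truth)
  a_max <- sqrt(max(config$g2_area_range_points[2],
                    config$g1_area_range_points[2]) / config$points_scale /
                  (pi * config$axis_ratio_range[1]))
  pitch <- 2 * a_max + 8
  ncol_s <- floor(config$field_width / pitch)
  nrow_s <- floor(config$field_height / pitch)
  capacity <- ncol_s * nrow_s
  if (capacity < 1)
    stop("generator_config: field too small for the configured nucleus sizes")
  per_field <- min(config$cells_per_field, capacity)
  n_fields <- ceiling(n / per_field)

  area_px <- truth$true_area_points / config$points_scale
  semi_a <- sqrt(area_px / (pi * truth$axis_ratio))
  semi_b <- semi_a * truth$axis_ratio

  field <- integer(n); cx <- numeric(n); cy <- numeric(n)
  i <- 1L
  x0 <- (config$field_width - ncol_s * pitch) / 2
  y0 <- (config$field_height - nrow_s * pitch) / 2
  for (f in seq_len(n_fields)) {
    k <- min(per_field, n - (f - 1L) * per_field)
    slots <- sample(capacity, k)
    sx <- x0 + ((slots - 1) %% ncol_s) * pitch + pitch / 2
    sy <- y0 + ((slots - 1) %/% ncol_s) * pitch + pitch / 2
    for (j in seq_len(k)) {
      idx <- i + j - 1L
      field[idx] <- f
      jit <- max(0, pitch / 2 - semi_a[idx] - 3)
      cx[idx] <- sx[j] + runif(1, -jit, jit)
      cy[idx] <- sy[j] + runif(1, -jit, jit)
    }
    i <- i + k
  }

  ## touching mode: pull consecutive same-field cells against each other so
  ## their masks overlap (centre distance below the sum of minor semi-axes)
  n_pairs <- floor(config$touching_fraction * n / 2)
  for (p in seq_len(n_pairs)) {
    idx <- 2L * p - 1L
    if (idx + 1L > n || field[idx] != field[idx + 1L]) next
    theta <- runif(1, 0, 2 * pi)
    d <- 0.9 * (semi_b[idx] + semi_b[idx + 1L])
    cx[idx + 1L] <- cx[idx] + d * cos(theta)
    cy[idx + 1L] <- cy[idx] + d * sin(theta)
  }
  ## clamp everything safely inside the field
  pad <- semi_a + 2
  cx <- pmin(pmax(cx, pad), config$field_width - pad)
  cy <- pmin(pmax(cy, pad), config$field_height - pad)

  truth$field_id <- sprintf("F%02d", field)
  truth$center_x <- cx
  truth$center_y <- cy
  truth$semi_major_px <- semi_a
  truth$semi_minor_px <- semi_b
  truth
}

## ---- rendering primitives -------------------------------------------------

## logical mask of a rotated ellipse on the local window grid
.ellipse_mask <- function(rows, cols, cx, cy, a, b, theta, scale = 1) {
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / (a * scale))^2 + (yr / (b * scale))^2 <= 1
}

.window <- function(c0, half, lim) {
  lo <- max(1L, floor(c0 - half))
  hi <- min(lim, ceiling(c0 + half))
  lo:hi
}

## per-plane amplitude profile of an axially Gaussian object centred at z0_um
.z_weights <- function(z0_um, config, sigma_z) {
  zs <- (seq_len(config$z_planes) - 1) * config$z_step_um
  exp(-((zs - z0_um)^2) / (2 * sigma_z^2))
}

## unit-amplitude 2-D Gaussian patch on the local window grid
.blob_patch <- function(rows, cols, x, y, sigma) {
  exp(-(outer((rows - y)^2, (cols - x)^2, "+")) / (2 * sigma^2))
}

## place k points inside the (scaled) nucleus ellipse; when min_sep > 0 use
## dart throwing with a best-effort fallback for crowded nuclei
.place_in_ellipse <- function(k, cx, cy, a, b, theta, min_sep = 0,
                              scale = 0.85) {
  if (k == 0) return(cbind(x = numeric(0), y = numeric(0)))
  draw1 <- function() {
    repeat {
      u <- runif(1, -1, 1); v <- runif(1, -1, 1)
      if (u^2 + v^2 <= 1) break
    }
    xr <- u * a * scale; yr <- v * b * scale
    c(cx + xr * cos(theta) - yr * sin(theta),
      cy + xr * sin(theta) + yr * cos(theta))
  }
  pts <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    if (min_sep <= 0 || i == 1) {
      pts[i, ] <- draw1()
    } else {
      best <- NULL; best_d <- -Inf
      for (try in seq_len(200)) {
        p <- draw1()
        d <- min(sqrt((pts[seq_len(i - 1), 1] - p[1])^2 +
                        (pts[seq_len(i - 1), 2] - p[2])^2))
        if (d >= min_sep) { best <- p; best_d <- d; break }
        if (d > best_d) { best <- p; best_d <- d }
      }
      pts[i, ] <- best
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

## smoothed lognormal texture for the rough S-phase pattern
.s_texture <- function(nr, nc, mask, config) {
  tex <- matrix(rnorm(nr * nc), nr, nc)
  k <- .gauss_kernel_2d(1.5)
  tex <- EBImage::filter2(tex, k, boundary = "replicate")
  mu <- mean(tex[mask]); s <- sd(tex[mask])
  if (!is.finite(s) || s == 0) s <- 1
  v <- config$s_base_intensity * exp(config$s_sdlog * (tex - mu) / s)
  pmin(v, 60000)
}

.gauss_kernel_2d <- function(sigma) {
  r <- ceiling(2.5 * sigma)
  g <- dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

## ---- field rendering ------------------------------------------------------

.render_field <- function(truth_f, config, field_id) {
  h <- config$field_height; w <- config$field_width
  Z <- config$z_planes
  arr <- array(0, c(h, w, Z, 3))
  depth <- (Z - 1) * config$z_step_um

  sigma_p <- config$pericentrin_diameter_px * .FWHM_TO_SIGMA
  dose <- if (nrow(truth_f)) truth_f$dose_Gy[1] else 0
  fwhm_f <- config$focus_diameter_base_px + config$focus_diameter_per_Gy * dose
  sigma_f <- fwhm_f * .FWHM_TO_SIGMA
  peak_f <- config$focus_peak_intensity_base +
    config$focus_peak_intensity_per_Gy * dose

  for (i in seq_len(nrow(truth_f))) {
    cell <- truth_f[i, ]
    a <- cell$semi_major_px; b <- cell$semi_minor_px
    th <- cell$angle_rad
    rows <- .window(cell$center_y, a + 2, h)
    cols <- .window(cell$center_x, a + 2, w)
    M <- .ellipse_mask(rows, cols, cell$center_x, cell$center_y, a, b, th)

    ## DAPI: hard-edged ellipse, axially attenuated
    z_mid <- depth / 2 + runif(1, -0.5, 0.5)
    fz_nuc <- .z_weights(z_mid, config, config$nucleus_sigma_z_um)
    for (zi in seq_len(Z)) {
      arr[rows, cols, zi, 1] <- arr[rows, cols, zi, 1] +
        cell$dapi_level * fz_nuc[zi] * M
    }

    ## gamma-H2AX
    if (cell$true_phase %in% c("G1", "G2")) {
      k <- cell$true_focus_count
      if (k > 0) {
        min_sep <- if (config$allow_focus_overlap) 0 else
          config$focus_min_separation_fwhm * fwhm_f
        pts <- .place_in_ellipse(k, cell$center_x, cell$center_y, a, b, th,
                                 min_sep = min_sep)
        for (j in seq_len(k)) {
          amp <- peak_f * max(0.2, 1 + config$focus_peak_cv * rnorm(1))
          z0 <- runif(1, 0, depth)
          fz <- amp * .z_weights(z0, config, config$focus_sigma_z_um)
          fr <- .window(pts[j, 2], 3.5 * sigma_f, h)
          fc <- .window(pts[j, 1], 3.5 * sigma_f, w)
          g <- .blob_patch(fr, fc, pts[j, 1], pts[j, 2], sigma_f)
          for (zi in which(fz > 1))
            arr[fr, fc, zi, 2] <- arr[fr, fc, zi, 2] + fz[zi] * g
        }
      }
    } else if (cell$true_phase == "S") {
      tex <- .s_texture(length(rows), length(cols), M, config)
      for (zi in seq_len(Z)) {
        arr[rows, cols, zi, 2] <- arr[rows, cols, zi, 2] +
          tex * fz_nuc[zi] * M
      }
    } else { # M: bright, uniform pan-nuclear staining
      v <- config$m_level * pmax(0, 1 + config$m_cv *
                                   matrix(rnorm(length(rows) * length(cols)),
                                          length(rows)))
      for (zi in seq_len(Z)) {
        arr[rows, cols, zi, 2] <- arr[rows, cols, zi, 2] + v * fz_nuc[zi] * M
      }
    }

    ## pericentrin: 1 or 2 spots near the nuclear periphery
    npc <- cell$true_pericentrin_count
    peak_each <- (cell$true_pericentrin_intensity /
                    (2 * pi * sigma_p^2)) / npc
    dir0 <- runif(1, 0, 2 * pi)
    for (j in seq_len(npc)) {
      ang <- dir0 + (j - 1) * pi + runif(1, -0.3, 0.3)
      rad <- runif(1, 0.35, 0.8)
      xr <- rad * a * cos(ang) * 0.9; yr <- rad * b * sin(ang) * 0.9
      px <- cell$center_x + xr * cos(th) - yr * sin(th)
      py <- cell$center_y + xr * sin(th) + yr * cos(th)
      z0 <- runif(1, 0, depth)
      fz <- peak_each * .z_weights(z0, config, config$focus_sigma_z_um)
      pr <- .window(py, 3.5 * sigma_p, h)
      pc <- .window(px, 3.5 * sigma_p, w)
      g <- .blob_patch(pr, pc, px, py, sigma_p)
      for (zi in which(fz > 1))
        arr[pr, pc, zi, 3] <- arr[pr, pc, zi, 3] + fz[zi] * g
    }
  }

  arr <- arr + config$background_offset
  if (config$noise_sd > 0)
    arr <- arr + rnorm(length(arr), 0, config$noise_sd)
  arr <- round(pmin(pmax(arr, 0), 65535))
  storage.mode(arr) <- "integer"
  dimnames(arr) <- list(NULL, NULL, NULL, c("DAPI", "gH2AX", "pericentrin"))

  structure(list(pixels = arr,
                 pixel_size_um = config$pixel_size_um,
                 z_step_um = config$z_step_um,
                 field_id = field_id),
            class = "zstack_field")
}

#' Generate one synthetic sample (fields plus ground truth)
#'
#' Draws the cell population with [simulate_ground_truth()], lays nuclei out
#' on a non-touching grid (or with a configurable fraction of touching pairs)
#' and renders the three-channel z-stack fields: hard-edged elliptical DAPI
#' nuclei, gamma-H2AX foci as isotropic 3-D Gaussians sampled onto the focal
#' planes, pan-nuclear S/M patterns, and 1-2 peripheral pericentrin spots
#' per cell. Output is bit-identical for identical configuration and seed.
#'
#' @param config A [generator_config()].
#' @param dose_Gy Dose of the sample; must be listed in `config$doses_Gy`.
#' @return A list with elements `fields` (list of `zstack_field`) and
#'   `truth` (the ground-truth data.frame, one row per cell, including the
#'   layout columns `field_id`, `center_x`, `center_y`).
#' @examples
#' cfg <- generator_config(cells_per_dose = 4, cells_per_field = 4,
#'                         field_width = 512, field_height = 512,
#'                         doses_Gy = 0, seed = 7)
#' s <- generate_sample(cfg, 0)
#' nrow(s$truth)
#' @export
generate_sample <- function(config, dose_Gy) {
  stopifnot(inherits(config, "generator_config"))
  if (!any(abs(config$doses_Gy - dose_Gy) < 1e-9))
    stop("dose_Gy must be one of config$doses_Gy")
  set.seed(.gen_seed(config, dose_Gy))
  truth <- .simulate_truth_body(config, dose_Gy, config$cells_per_dose)
  if (nrow(truth) == 0)
    return(list(fields = list(), truth = truth))
  truth <- .layout_sample(truth, config)
  fields <- lapply(unique(truth$field_id), function(fid) {
    .render_field(truth[truth$field_id == fid, , drop = FALSE], config, fid)
  })
  list(fields = fields, truth = truth)
}

#' Render a single S- or M-pattern cell
#'
#' S-phase cells show a rough, granulated gamma-H2AX signal across most of
#' the nucleus; M-phase cells are uniformly and brightly pan-nuclear and
#' carry exactly two separated pericentrin spots. This helper renders one
#' such cell on a small dedicated field, with its ground truth attached as
#' the `"ground_truth"` attribute.
#'
#' @param phase `"S"` or `"M"`.
#' @param config A [generator_config()]; the seed controls all randomness.
#' @return A `zstack_field` containing one nucleus.
#' @export
render_pattern_cell <- function(phase, config) {
  stopifnot(inherits(config, "generator_config"))
  if (!phase %in% c("S", "M"))
    stop("render_pattern_cell: phase must be \"S\" or \"M\"")
  set.seed(.gen_seed(config, if (phase == "S") 9001 else 9002))
  rng <- if (phase == "S") config$g1_area_range_points else
    config$g2_area_range_points
  area <- runif(1, rng[1], rng[2])
  ratio <- runif(1, config$axis_ratio_range[1], config$axis_ratio_range[2])
  a <- sqrt(area / config$points_scale / (pi * ratio))
  side <- 2 * ceiling(a) + 40
  truth <- data.frame(
    cell_id = "c00001", dose_Gy = 0, true_phase = phase,
    true_area_points = area, true_focus_count = 0L,
    true_pericentrin_count = if (phase == "M") 2L else 1L,
    true_pericentrin_intensity = mean(c(config$pericentrin_peak_min,
                                        config$pericentrin_peak_max)) *
      2 * pi * (config$pericentrin_diameter_px * .FWHM_TO_SIGMA)^2,
    axis_ratio = ratio, angle_rad = runif(1, 0, pi),
    dapi_level = config$dapi_level,
    field_id = "F01", center_x = side / 2, center_y = side / 2,
    semi_major_px = a, semi_minor_px = a * ratio,
    stringsAsFactors = FALSE)
  cfg <- config
  cfg$field_width <- side
  cfg$field_height <- side
  fld <- .render_field(truth, cfg, "F01")
  attr(fld, "ground_truth") <- truth
  fld
}
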