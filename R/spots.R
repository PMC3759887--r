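## Per-plane spot detection with cross-plane merging.
##
## Detection is a difference-of-Gaussians band-pass followed by a fixed
## threshold; each connected supra-threshold footprint is one spot. Two foci
## whose footprints merge at the detection threshold are therefore returned
## as ONE spot - this mirrors the behaviour of the scanning system and is
## the mechanism behind count saturation at high dose, so it is preserved,
## not corrected. Thresholds are constant per run; no per-field adaptation.

.dog_kernel <- function(sigma, sigma_bg) {
  r <- ceiling(2.5 * sigma_bg)
  g1 <- dnorm(-r:r, sd = sigma); g1 <- outer(g1, g1); g1 <- g1 / sum(g1)
  g2 <- dnorm(-r:r, sd = sigma_bg); g2 <- outer(g2, g2); g2 <- g2 / sum(g2)
  g1 - g2
}

## FFT of the band-pass kernel, zero-padded to the image geometry and
## centred at the origin; cached per (geometry, bandwidth) because the same
## kernel is reused across planes, channels and fields of a run
.dog_cache <- new.env(parent = emptyenv())

.dog_kernel_fft <- function(h, w, sigma, sigma_bg) {
  key <- paste(h, w, sigma, sigma_bg, sep = "_")
  hit <- .dog_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- .dog_kernel(sigma, sigma_bg)
  r <- (nrow(k) - 1L) %/% 2L
  pad <- matrix(0, h, w)
  pad[1:nrow(k), 1:ncol(k)] <- k
  ## circular shift so the kernel centre sits at the origin
  pad <- pad[c((r + 1):h, 1:r), c((r + 1):w, 1:r)]
  K <- fftwtools::fftw2d(pad)
  .dog_cache[[key]] <- K
  K
}

## band-pass by cyclic convolution; the kernel integrates to ~0, so the
## wrap-around at the borders only mixes in near-zero background response
.dog_filter <- function(img, settings) {
  K <- .dog_kernel_fft(nrow(img), ncol(img), settings$dog_sigma_px,
                       settings$dog_background_sigma_px)
  Re(fftwtools::fftw2d(fftwtools::fftw2d(img) * K, inverse = 1)) /
    length(img)
}

.dilate_labels <- function(labels, px) {
  if (px <= 0) return(labels)
  brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, "disc")
  d <- EBImage::imageData(EBImage::dilate(EBImage::Image(labels), brush))
  matrix(as.integer(round(d)), nrow(labels), ncol(labels))
}

## connected-component statistics of one thresholded plane
.plane_components <- function(img, dog, thr, z) {
  mask <- dog > thr
  if (!any(mask)) return(NULL)
  L <- EBImage::imageData(EBImage::bwlabel(mask))
  idx <- which(L > 0)
  labs <- L[idx]
  h <- nrow(img)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  raw <- as.numeric(img[idx])
  area <- tabulate(labs)
  n <- length(area)
  bg <- median(img[seq(1L, length(img), by = 13L)])
  sp <- split(seq_along(labs), labs)
  vmax <- vapply(sp, function(ii) max(raw[ii]), numeric(1))
  vmin <- vapply(sp, function(ii) min(raw[ii]), numeric(1))
  data.frame(
    z_plane = z,
    x = rowsum(as.numeric(cols), labs)[, 1] / area,
    y = rowsum(as.numeric(rows), labs)[, 1] / area,
    diameter_px = 2 * sqrt(area / pi),
    intensity_min = vmin,
    intensity_max = vmax,
    integrated_intensity = pmax(0, rowsum(raw, labs)[, 1] - area * bg),
    stringsAsFactors = FALSE)
}

## merge per-plane detections whose xy centroids fall within merge_radius on
## adjacent planes; a spot spanning several planes is counted once
.merge_planes <- function(df, merge_radius) {
  if (is.null(df) || nrow(df) == 0) return(df)
  df$cluster <- 0L
  next_cluster <- 0L
  prev <- NULL
  prev_z <- -Inf
  for (z in sort(unique(df$z_plane))) {
    if (z - prev_z > 1L) prev <- NULL
    cur <- which(df$z_plane == z)
    taken <- rep(FALSE, length(prev))
    for (i in cur) {
      assigned <- FALSE
      if (length(prev)) {
        dd <- sqrt((df$x[prev] - df$x[i])^2 + (df$y[prev] - df$y[i])^2)
        dd[taken] <- Inf
        j <- which.min(dd)
        if (length(j) && dd[j] <= merge_radius) {
          df$cluster[i] <- df$cluster[prev[j]]
          taken[j] <- TRUE
          assigned <- TRUE
        }
      }
      if (!assigned) {
        next_cluster <- next_cluster + 1L
        df$cluster[i] <- next_cluster
      }
    }
    prev <- cur
    prev_z <- z
  }
  out <- do.call(rbind, lapply(split(df, df$cluster), function(g) {
    b <- which.max(g$intensity_max)
    data.frame(x = g$x[b], y = g$y[b], z_plane = g$z_plane[b],
               n_planes = nrow(g),
               diameter_px = max(g$diameter_px),
               intensity_min = min(g$intensity_min),
               intensity_max = max(g$intensity_max),
               integrated_intensity = sum(g$integrated_intensity),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.empty_focus_table <- function() {
  data.frame(focus_id = character(), channel = character(),
             nucleus_id = character(), x = numeric(), y = numeric(),
             z_plane = integer(), n_planes = integer(),
             diameter_px = numeric(), intensity_min = numeric(),
             intensity_max = numeric(), integrated_intensity = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect gamma-H2AX foci or pericentrin spots in one field
#'
#' Spots are detected independently on every focal plane (band-pass +
#' threshold-connected footprint), then merged across adjacent planes when
#' their xy centroids fall within `merge_radius_px`, so a spot visible in
#' several planes is counted once. Each merged spot is assigned to the
#' nucleus whose mask contains its centroid; for pericentrin the masks are
#' first dilated by `pericentrin_dilation_px`, because the centrosome sits
#' beside the nucleus and often only overlaps its border. Spots falling in
#' no nucleus are discarded.
#'
#' @param field A `zstack_field`.
#' @param nuclei The [segment_nuclei()] output for the same field.
#' @param channel `"gH2AX"` or `"pericentrin"`.
#' @param settings A [capture_settings()].
#' @return A data.frame of focus records: `focus_id`, `channel`,
#'   `nucleus_id`, `x`, `y`, `z_plane`, `n_planes`, `diameter_px`,
#'   `intensity_min`, `intensity_max`, `integrated_intensity`.
#' @export
detect_spots <- function(field, nuclei, channel = c("gH2AX", "pericentrin"),
                         settings = capture_settings()) {
  .check_field(field)
  channel <- match.arg(channel)
  if (!inherits(nuclei, "nucleus_set"))
    stop("nuclei must be a nucleus_set")
  if (!identical(nuclei$field_id, field$field_id))
    stop("nuclei were segmented from a different field")

  ch_i <- if (channel == "gH2AX") 2L else 3L
  thr <- if (channel == "gH2AX") settings$gH2AX_threshold else
    settings$pericentrin_threshold

  Z <- dim(field$pixels)[3]
  planes <- vector("list", Z)
  for (z in seq_len(Z)) {
    img <- field$pixels[, , z, ch_i]
    storage.mode(img) <- "double"
    dog <- .dog_filter(img, settings)
    planes[[z]] <- .plane_components(img, dog, thr, z)
  }
  df <- do.call(rbind, planes)
  if (is.null(df) || nrow(df) == 0) return(.empty_focus_table())
  df <- .merge_planes(df, settings$merge_radius_px)

  lab_img <- nuclei$labels
  if (channel == "pericentrin")
    lab_img <- .dilate_labels(lab_img, settings$pericentrin_dilation_px)
  h <- nrow(lab_img); w <- ncol(lab_img)
  ri <- pmin(pmax(round(df$y), 1L), h)
  ci <- pmin(pmax(round(df$x), 1L), w)
  lab <- lab_img[cbind(ri, ci)]
  df <- df[lab > 0, , drop = FALSE]
  lab <- lab[lab > 0]
  if (!nrow(df)) return(.empty_focus_table())

  stopifnot(all(df$intensity_min <= df$intensity_max))
  out <- data.frame(
    focus_id = sprintf("%s_%s_S%04d", field$field_id,
                       if (channel == "gH2AX") "g" else "p",
                       seq_len(nrow(df))),
    channel = channel,
    nucleus_id = nuclei$table$nucleus_id[match(lab, nuclei$table$label)],
    df[, c("x", "y", "z_plane", "n_planes", "diameter_px",
           "intensity_min", "intensity_max", "integrated_intensity")],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Maximum spot-diameter acceptance gate
#'
#' Accepts a spot iff its footprint diameter does not exceed
#' `reference_diameter_px * spot_diameter_pct / 100` (boundary inclusive).
#' With the default 280% gate, oversized objects (e.g. large debris or
#' fused multi-focus clusters far above the reference size) are rejected
#' while ordinary and moderately merged foci pass.
#'
#' @param spot A focus-record data.frame (one or more rows) as returned by
#'   [detect_spots()].
#' @param settings A [capture_settings()] providing `spot_diameter_pct`.
#' @param reference_diameter_px Reference spot diameter, pixels, positive.
#' @return Logical vector, `TRUE` for accepted rows.
#' @examples
#' s <- data.frame(diameter_px = c(5, 5.7))
#' max_diameter_filter(s, capture_settings(), reference_diameter_px = 2)
#' @export
max_diameter_filter <- function(spot, settings = capture_settings(),
                                reference_diameter_px =
                                  settings$reference_diameter_px) {
  if (!is.numeric(reference_diameter_px) || reference_diameter_px <= 0)
    stop("reference_diameter_px must be positive")
  d <- if (is.data.frame(spot)) spot$diameter_px else as.numeric(spot)
  d <= reference_diameter_px * settings$spot_diameter_pct / 100
}

#' Intensity of the brightest focus of a cell
#'
#' Returns the maximum `intensity_max` over a cell's foci, or 0 when the
#' cell has none. The per-sample mean of this quantity grows with dose and
#' is used to diagnose focus-overlap saturation.
#'
#' @param nucleus_foci Focus-record data.frame of one nucleus (may be
#'   empty).
#' @return Non-negative number.
#' @export
brightest_focus_intensity <- function(nucleus_foci) {
  if (is.null(nucleus_foci) || nrow(nucleus_foci) == 0) return(0)
  max(nucleus_foci$intensity_max)
}
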