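## DAPI nucleus segmentation and area measurement.

.max_project <- function(stack3d) {
  Z <- dim(stack3d)[3]
  m <- stack3d[, , 1]
  if (Z > 1) for (zi in 2:Z) m <- pmax(m, stack3d[, , zi])
  m
}

.check_field <- function(field) {
  if (!inherits(field, "zstack_field"))
    stop("expected a zstack_field")
  d <- dim(field$pixels)
  if (length(d) != 4L || d[4] != 3L)
    stop("field geometry mismatch: pixels must be height x width x z x 3")
  invisible(d)
}

#' Convert nuclear area from pixels to scanner "points"
#'
#' The scanning system stores nuclear area in a proprietary linear unit
#' ("points"); only linearity is assumed here, with a single configurable
#' scale factor. The default gates (50/130/250 points) refer to this unit.
#'
#' @param area_px Pixel area(s), positive.
#' @param points_scale Positive linear conversion factor.
#' @return `area_px * points_scale`.
#' @examples
#' area_in_points(1000, 0.1)
#' @export
area_in_points <- function(area_px, points_scale) {
  if (!is.numeric(points_scale) || length(points_scale) != 1L ||
      !is.finite(points_scale) || points_scale <= 0)
    stop("points_scale must be a positive number")
  if (!is.numeric(area_px) || any(!is.finite(area_px)) || any(area_px <= 0))
    stop("area_px must be positive")
  area_px * points_scale
}

#' Segment nuclei from the DAPI channel
#'
#' Nuclei are detected on the maximum-intensity projection of the DAPI
#' channel with an Otsu threshold, hole filling, connected-component
#' labelling and a minimum-size prefilter at the debris gate. No watershed
#' splitting is attempted: touching nuclei are left merged on purpose and
#' rejected downstream through their pericentrin count and area class.
#' Objects touching the field border are flagged `boundary_touching`; the
#' scoring pipeline excludes them.
#'
#' @param field A `zstack_field`.
#' @param settings A [capture_settings()]; `points_scale` and
#'   `min_nucleus_points` are used here.
#' @return A `nucleus_set`: list with `labels` (integer label matrix, 0 =
#'   background), `table` (one row per nucleus: `nucleus_id`, `label`,
#'   `area_px`, `area_points`, `centroid_x`, `centroid_y`, `dapi_mean`,
#'   `boundary_touching`) and `field_id`.
#' @export
segment_nuclei <- function(field, settings = capture_settings()) {
  d <- .check_field(field)
  h <- d[1]; w <- d[2]
  proj <- .max_project(field$pixels[, , , 1, drop = TRUE])
  empty <- structure(list(labels = matrix(0L, h, w),
                          table = .empty_nucleus_table(),
                          field_id = field$field_id,
                          points_scale = settings$points_scale),
                     class = "nucleus_set")
  if (all(proj == 0)) return(empty)

  v <- proj / 65535
  thr <- EBImage::otsu(EBImage::Image(v), range = c(0, 1))
  mask <- v > thr
  ## a blank field (uniform background) thresholds to a quasi-global
  ## foreground; real nuclei never cover most of the field
  if (mean(mask) > 0.6) return(empty)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask)))
  L <- EBImage::imageData(EBImage::bwlabel(mask))

  idx <- which(L > 0)
  if (!length(idx)) return(empty)
  labs <- L[idx]
  sizes <- tabulate(labs)
  min_px <- settings$min_nucleus_points / settings$points_scale
  keep <- which(sizes >= min_px)
  if (!length(keep)) return(empty)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  L2 <- matrix(0L, h, w)
  kept <- remap[labs] > 0L
  idx <- idx[kept]
  labs2 <- remap[labs[kept]]
  L2[idx] <- labs2

  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  area_px <- tabulate(labs2)
  cx <- rowsum(as.numeric(cols), labs2)[, 1] / area_px
  cy <- rowsum(as.numeric(rows), labs2)[, 1] / area_px
  dapi_mean <- rowsum(as.numeric(proj[idx]), labs2)[, 1] / area_px
  border_labs <- unique(c(L2[1, ], L2[h, ], L2[, 1], L2[, w]))
  boundary <- seq_along(keep) %in% border_labs

  tbl <- data.frame(
    nucleus_id = sprintf("%s_N%03d", field$field_id, seq_along(keep)),
    label = seq_along(keep),
    area_px = area_px,
    area_points = area_in_points(area_px, settings$points_scale),
    centroid_x = cx, centroid_y = cy,
    dapi_mean = dapi_mean,
    boundary_touching = boundary,
    stringsAsFactors = FALSE)
  structure(list(labels = L2, table = tbl, field_id = field$field_id,
                 points_scale = settings$points_scale),
            class = "nucleus_set")
}

.empty_nucleus_table <- function() {
  data.frame(nucleus_id = character(), label = integer(),
             area_px = integer(), area_points = numeric(),
             centroid_x = numeric(), centroid_y = numeric(),
             dapi_mean = numeric(), boundary_touching = logical(),
             stringsAsFactors = FALSE)
}
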