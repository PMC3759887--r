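## Scoring pipeline: segment -> detect -> classify -> summarise.

#' Score one field
#'
#' Runs nucleus segmentation, spot detection on both probe channels, the
#' maximum-diameter gate, and per-nucleus classification for a single
#' field. Deterministic given the field and settings.
#'
#' @param field A `zstack_field`.
#' @param settings A [capture_settings()].
#' @param gates An [area_gates()].
#' @return List with `nuclei` (per-nucleus table), `spots` (accepted focus
#'   records of both channels) and `cells` (classification table).
#' @export
score_field <- function(field, settings = capture_settings(),
                        gates = area_gates()) {
  nuclei <- segment_nuclei(field, settings)
  if (nrow(nuclei$table) == 0) {
    return(list(nuclei = nuclei$table, spots = .empty_focus_table(),
                cells = .empty_classification()))
  }
  sg <- detect_spots(field, nuclei, "gH2AX", settings)
  sp <- detect_spots(field, nuclei, "pericentrin", settings)
  sg <- sg[max_diameter_filter(sg, settings), , drop = FALSE]
  sp <- sp[max_diameter_filter(sp, settings), , drop = FALSE]
  proj_g <- .max_project(field$pixels[, , , 2, drop = TRUE])
  cells <- classify_cells(nuclei, sg, sp, proj_g, gates, settings)
  list(nuclei = nuclei$table, spots = rbind(sg, sp), cells = cells)
}

#' Score a whole sample
#'
#' Applies [score_field()] to every field of a sample and aggregates the
#' per-cell results into a [summarize_sample()] summary.
#'
#' @param fields List of `zstack_field`s (e.g. `generate_sample()$fields`).
#' @param settings A [capture_settings()].
#' @param gates An [area_gates()].
#' @param sample_id,dose_Gy Sample identifiers for the summary.
#' @param minimum_nuclei QC minimum of valid nuclei (default 1000).
#' @param stratify Stratify summaries by area class?
#' @param keep_spots Keep the per-spot table (can be large)?
#' @return List of class `scored_sample` with `cells`, `nuclei`, `spots`
#'   (optional) and `summary`.
#' @export
score_sample <- function(fields, settings = capture_settings(),
                         gates = area_gates(), sample_id = "sample",
                         dose_Gy = NA_real_, minimum_nuclei = 1000,
                         stratify = TRUE, keep_spots = FALSE) {
  res <- lapply(fields, score_field, settings = settings, gates = gates)
  cells <- do.call(rbind, lapply(res, `[[`, "cells"))
  nuclei <- do.call(rbind, lapply(res, `[[`, "nuclei"))
  out <- list(
    cells = cells,
    nuclei = nuclei,
    summary = summarize_sample(cells, stratify = stratify,
                               sample_id = sample_id, dose_Gy = dose_Gy,
                               minimum_nuclei = minimum_nuclei,
                               max_foci_class = settings$max_foci_class))
  if (keep_spots) out$spots <- do.call(rbind, lapply(res, `[[`, "spots"))
  structure(out, class = "scored_sample")
}

#' Barplot of a sample's focus-count distribution
#'
#' @param x A `sample_result`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_foci_histogram <- function(x, ...) {
  graphics::barplot(x$foci_histogram,
                    xlab = "gamma-H2AX foci per cell", ylab = "cells",
                    main = sprintf("%s (%s Gy)", x$sample_id,
                                   format(x$dose_Gy)), ...)
  invisible(x)
}
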