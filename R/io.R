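## TIFF / CSV / YAML import-export.
##
## Fields are stored as multi-page 16-bit TIFF, plane-major: for each focal
## plane the three channels follow in the order DAPI, gamma-H2AX,
## pericentrin.

#' Write a field to a multi-page 16-bit TIFF
#'
#' @param field A `zstack_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  .check_field(field)
  d <- dim(field$pixels)
  pages <- vector("list", d[3] * 3L)
  k <- 1L
  for (z in seq_len(d[3])) {
    for (ch in 1:3) {
      pages[[k]] <- field$pixels[, , z, ch] / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a field from a multi-page TIFF
#'
#' Expects the plane-major page layout written by [write_field_tiff()]
#' (channels DAPI, gamma-H2AX, pericentrin within each plane).
#'
#' @param path TIFF file path.
#' @param field_id Identifier to attach (defaults to the file name).
#' @param pixel_size_um,z_step_um Spatial metadata to attach.
#' @param n_channels Channels per plane (3).
#' @return A `zstack_field`.
#' @export
read_field_tiff <- function(path, field_id = NULL, pixel_size_um = 0.1075,
                            z_step_um = 2.1, n_channels = 3L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% n_channels != 0L)
    stop("page count of '", path, "' is not a multiple of ", n_channels)
  Z <- length(pages) %/% n_channels
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0L, c(h, w, Z, n_channels))
  k <- 1L
  for (z in seq_len(Z)) {
    for (ch in seq_len(n_channels)) {
      arr[, , z, ch] <- as.integer(round(pages[[k]] * 65535))
      k <- k + 1L
    }
  }
  dimnames(arr) <- list(NULL, NULL, NULL,
                        c("DAPI", "gH2AX", "pericentrin")[seq_len(n_channels)])
  structure(list(pixels = arr, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 field_id = if (is.null(field_id))
                   sub("\\.tiff?$", "", basename(path)) else field_id),
            class = "zstack_field")
}

#' Write a generated sample to disk
#'
#' Writes one TIFF per field (`field_<id>.tif`), the ground-truth table
#' (`truth.csv`) and a YAML copy of the generator configuration
#' (`config.yaml`).
#'
#' @param sample Output of [generate_sample()].
#' @param dir Output directory (created if missing).
#' @param config The [generator_config()] used (optional, for provenance).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in sample$fields)
    write_field_tiff(f, file.path(dir, sprintf("field_%s.tif", f$field_id)))
  write.csv(sample$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(.config_to_list(config), file.path(dir, "config.yaml"))
  invisible(dir)
}

.config_to_list <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$foci_rate_table))
    cfg$foci_rate_table <- as.list(cfg$foci_rate_table)
  cfg
}

.config_from_list <- function(lst) {
  if (!is.null(lst$foci_rate_table))
    lst$foci_rate_table <- as.data.frame(lst$foci_rate_table)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown generator configuration field(s): ",
         paste(unknown, collapse = ", "))
  do.call(generator_config, lst)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file with [generator_config()] fields.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  .config_from_list(yaml::read_yaml(path))
}
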