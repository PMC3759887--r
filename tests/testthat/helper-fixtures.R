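## Shared fixtures and independent oracles for the test suite.

## small, fast generator configuration for unit tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    doses_Gy = c(0, 0.5, 1), cells_per_dose = 12, cells_per_field = 16,
    field_width = 512, field_height = 512,
    s_fraction = 0, m_fraction = 0, seed = 42L)
  defaults[names(args)] <- args
  do.call(generator_config, defaults)
}

## hand-built z-stack field: flat background plus explicit ellipses/blobs,
## independent of the generator's rendering path
make_test_field <- function(h = 256, w = 256, Z = 4, background = 500,
                            field_id = "T01") {
  arr <- array(background, c(h, w, Z, 3))
  dimnames(arr) <- list(NULL, NULL, NULL, c("DAPI", "gH2AX", "pericentrin"))
  structure(list(pixels = arr, pixel_size_um = 0.1075, z_step_um = 2.1,
                 field_id = field_id),
            class = "zstack_field")
}

## stamp a filled ellipse into one channel of every z-plane
stamp_ellipse <- function(field, cx, cy, a, b = a, level = 15000, ch = 1) {
  d <- dim(field$pixels)
  for (r in max(1, floor(cy - a)):min(d[1], ceiling(cy + a))) {
    for (cc in max(1, floor(cx - a)):min(d[2], ceiling(cx + a))) {
      if (((cc - cx) / a)^2 + ((r - cy) / b)^2 <= 1)
        field$pixels[r, cc, , ch] <- level
    }
  }
  field
}

## stamp a 2-D Gaussian blob on selected z-planes of one channel
stamp_blob <- function(field, x, y, sigma, peak, ch = 2, planes = NULL) {
  d <- dim(field$pixels)
  if (is.null(planes)) planes <- seq_len(d[3])
  rows <- max(1, floor(y - 4 * sigma)):min(d[1], ceiling(y + 4 * sigma))
  cols <- max(1, floor(x - 4 * sigma)):min(d[2], ceiling(x + 4 * sigma))
  g <- peak * exp(-(outer((rows - y)^2, (cols - x)^2, "+")) / (2 * sigma^2))
  for (z in planes)
    field$pixels[rows, cols, z, ch] <- field$pixels[rows, cols, z, ch] +
      round(g)
  field
}

## independent Mann-Whitney oracle: U from direct pair counting, two-sided
## p from full enumeration of group assignments
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  U_of <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  U_obs <- U_of(x, y)
  pool <- c(x, y)
  mu <- n1 * n2 / 2
  sel <- utils::combn(n1 + n2, n1)
  Us <- apply(sel, 2, function(ii) U_of(pool[ii], pool[-ii]))
  p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  list(U = U_obs, p = p)
}

## OLS oracle by normal equations
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

## count connected supra-threshold components on the raw (not band-passed)
## max projection - used as an independent footprint-merge oracle
oracle_component_count <- function(field, ch = 2, thr = 2000) {
  d <- dim(field$pixels)
  proj <- field$pixels[, , 1, ch]
  if (d[3] > 1) for (z in 2:d[3]) proj <- pmax(proj, field$pixels[, , z, ch])
  L <- EBImage::imageData(EBImage::bwlabel(proj > thr))
  max(L)
}

## match scored nuclei back to ground-truth cells by centroid proximity;
## returns merged data.frame of cells plus their truth rows
match_cells_to_truth <- function(scored, truth, max_dist = 15) {
  nuc <- scored$nuclei
  cells <- merge(scored$cells, nuc[, c("nucleus_id", "centroid_x",
                                       "centroid_y")], by = "nucleus_id")
  cells$field_id <- sub("_N[0-9]+$", "", cells$nucleus_id)
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    tf <- truth[truth$field_id == cells$field_id[i], , drop = FALSE]
    if (!nrow(tf)) next
    dd <- sqrt((tf$center_x - cells$centroid_x[i])^2 +
                 (tf$center_y - cells$centroid_y[i])^2)
    j <- which.min(dd)
    if (dd[j] <= max_dist)
      out <- rbind(out, cbind(cells[i, , drop = FALSE],
                              tf[j, c("cell_id", "true_phase",
                                      "true_area_points", "true_focus_count",
                                      "true_pericentrin_count",
                                      "true_pericentrin_intensity"),
                                 drop = FALSE]))
  }
  out
}
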