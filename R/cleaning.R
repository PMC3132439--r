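#' Define an RGB colour range
#'
#' An inclusive per-channel box in RGB space. Any pixel whose three channel
#' values all fall inside the box is treated as background by
#' [clean_section()]. Soils, glares and salt/pepper noise usually occupy
#' different tonal regions, so several ranges can be combined.
#'
#' @param min,max length-3 integer vectors (R, G, B), each in 0..255 with
#'   `min <= max` per channel.
#' @return A `color_range` object.
#' @export
color_range <- function(min, max) {
  min <- as.integer(min); max <- as.integer(max)
  if (length(min) != 3L || length(max) != 3L)
    stopf("min and max must each have 3 channel values")
  if (any(min < 0L) || any(max > 255L)) stopf("channel bounds must lie in 0..255")
  if (any(min > max)) stopf("min must be <= max in every channel")
  structure(list(min = min, max = max), class = "color_range")
}

#' @export
print.color_range <- function(x, ...) {
  cat(sprintf("<color_range> R %d..%d, G %d..%d, B %d..%d\n",
              x$min[1], x$max[1], x$min[2], x$max[2], x$min[3], x$max[3]))
  invisible(x)
}

range_mask <- function(raster, rng) {
  raster[, , 1] >= rng$min[1] & raster[, , 1] <= rng$max[1] &
  raster[, , 2] >= rng$min[2] & raster[, , 2] <= rng$max[2] &
  raster[, , 3] >= rng$min[3] & raster[, , 3] <= rng$max[3]
}

#' Clean background soils and glares from a section
#'
#' Every pixel whose RGB value falls inside any of the supplied background
#' colour ranges is set to exact black `(0,0,0)`. Any surviving pixel that
#' was already exact black in the input is lifted to `(1,1,1)`: after
#' cleaning, "tissue" and "not `(0,0,0)`" are the same predicate, which the
#' centring, orientation, contour and volume stages all rely on. The lift is
#' visually invisible but keeps a genuinely black tissue pixel from being
#' silently reclassified as background.
#'
#' Cleaning is idempotent as long as `(0,0,0)` itself lies inside one of the
#' ranges or inside none that `(1,1,1)` also avoids; in all cases it never
#' increases the number of non-black pixels.
#'
#' @param image a [section_image()].
#' @param background_ranges list of [color_range()] objects (at least one).
#' @return The cleaned `section_image`.
#' @export
clean_section <- function(image, background_ranges) {
  if (inherits(background_ranges, "color_range"))
    background_ranges <- list(background_ranges)
  if (length(background_ranges) < 1L)
    stopf("at least one background colour range is required")
  raster <- image$raster
  bg <- Reduce(`|`, lapply(background_ranges, range_mask, raster = raster))
  black_in <- raster[, , 1] == 0L & raster[, , 2] == 0L & raster[, , 3] == 0L
  lift <- black_in & !bg
  for (ch in 1:3) {
    plane <- raster[, , ch]
    plane[bg] <- 0L
    plane[lift] <- 1L
    raster[, , ch] <- plane
  }
  out <- image
  out$raster <- raster
  out
}

#' Suggest background colour ranges from two sampling windows
#'
#' Mimics interactive range picking: the user drags one window over pure
#' background and one over tissue. The suggested range spans the per-channel
#' extremes observed in the background window, shrunk per channel so that it
#' excludes every tone observed in the tissue window. If a channel cannot be
#' shrunk (the tissue tones sit strictly inside, or cover, the background
#' interval), that channel keeps the background extremes and the channel is
#' flagged as a conflict.
#'
#' @param image a [section_image()].
#' @param background_window,tissue_window windows given as
#'   `list(x = c(x0, x1), y = c(y0, y1))` in 0-based inclusive pixel
#'   coordinates; must lie inside the frame, have positive area and not
#'   overlap.
#' @return `list(ranges = list(color_range), conflict = logical(3))`.
#' @export
suggest_ranges <- function(image, background_window, tissue_window) {
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  check_window <- function(w, what) {
    if (!is.list(w) || length(w$x) != 2L || length(w$y) != 2L)
      stopf("%s window must be list(x = c(x0, x1), y = c(y0, y1))", what)
    if (w$x[1] > w$x[2] || w$y[1] > w$y[2])
      stopf("%s window is degenerate", what)
    if (w$x[1] < 0 || w$y[1] < 0 || w$x[2] >= W || w$y[2] >= H)
      stopf("%s window lies outside the frame", what)
  }
  check_window(background_window, "background")
  check_window(tissue_window, "tissue")
  if (background_window$x[1] <= tissue_window$x[2] &&
      tissue_window$x[1] <= background_window$x[2] &&
      background_window$y[1] <= tissue_window$y[2] &&
      tissue_window$y[1] <= background_window$y[2])
    stopf("background and tissue windows overlap")
  crop <- function(w) image$raster[(w$y[1] + 1):(w$y[2] + 1),
                                   (w$x[1] + 1):(w$x[2] + 1), , drop = FALSE]
  bg <- crop(background_window); ti <- crop(tissue_window)
  lo <- integer(3); hi <- integer(3); conflict <- logical(3)
  for (ch in 1:3) {
    bmin <- min(bg[, , ch]); bmax <- max(bg[, , ch])
    tmin <- min(ti[, , ch]); tmax <- max(ti[, , ch])
    lo[ch] <- bmin; hi[ch] <- bmax
    if (tmax < bmin || tmin > bmax) next            # already disjoint
    if (tmin > bmin && tmax >= bmax) hi[ch] <- tmin - 1L   # tissue above
    else if (tmax < bmax && tmin <= bmin) lo[ch] <- tmax + 1L  # tissue below
    else conflict[ch] <- TRUE                        # inside or covering
  }
  list(ranges = list(color_range(lo, hi)), conflict = conflict)
}

#' Clean every section of a stack
#'
#' Applies [clean_section()] to each section and auto-excludes sections whose
#' post-cleaning tissue fraction falls below `min_tissue_frac` — the stack
#' analogue of discarding sections with overwhelming background damage.
#'
#' @param stack a [section_stack()].
#' @param background_ranges list of [color_range()] objects.
#' @param min_tissue_frac minimum fraction of frame pixels that must remain
#'   tissue for a section to stay retained (default 0.001).
#' @return The cleaned `section_stack` (provenance gains a `"clean"` entry).
#' @export
clean_stack <- function(stack, background_ranges, min_tissue_frac = 0.001) {
  npix <- prod(dim(stack$sections[[1]]$raster)[1:2])
  for (k in seq_along(stack$sections)) {
    s <- clean_section(stack$sections[[k]], background_ranges)
    if (sum(tissue_mask(s$raster)) < min_tissue_frac * npix) s$excluded <- TRUE
    stack$sections[[k]] <- s
  }
  add_provenance(stack, "clean")
}
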