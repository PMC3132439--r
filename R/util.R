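# Internal helpers shared across stages.

# Frame centre of a W x H raster, 0-based pixel coordinates.
frame_center <- function(W, H) c((W - 1) / 2, (H - 1) / 2)

# Logical H x W tissue mask: any channel non-zero. Valid after cleaning,
# where background is exactly (0,0,0) by contract.
tissue_mask <- function(raster) {
  raster[, , 1] != 0L | raster[, , 2] != 0L | raster[, , 3] != 0L
}

# Rec. 601 luminance, rounded to integer; black background contributes 0.
luminance <- function(raster) {
  matrix(as.integer(round(0.299 * raster[, , 1] +
                          0.587 * raster[, , 2] +
                          0.114 * raster[, , 3])),
         nrow = dim(raster)[1])
}

as_raster_array <- function(raster) {
  if (!is.array(raster) || length(dim(raster)) != 3L || dim(raster)[3] != 3L)
    stop("raster must be an H x W x 3 array", call. = FALSE)
  if (anyNA(raster)) stop("raster contains NA values", call. = FALSE)
  storage.mode(raster) <- "integer"
  if (min(raster) < 0L || max(raster) > 255L)
    stop("raster channel values must lie in 0..255", call. = FALSE)
  raster
}

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(theta) {
  w <- theta %% 360
  ifelse(w > 180, w - 360, w)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
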