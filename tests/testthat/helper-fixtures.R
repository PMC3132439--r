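# Shared fixture builders. Everything is generated in code; no files.

# Background ranges covering the default phantom background (pale), salt,
# glare (all >= 200 per channel) and pepper/dark tones (<= 20 per channel).
std_ranges <- function() {
  list(color_range(c(200, 200, 200), c(255, 255, 255)),
       color_range(c(0, 0, 0), c(20, 20, 20)))
}

# Plain raster with a filled disk, built by direct indexing (independent of
# the phantom renderer). Centre in 0-based pixel coordinates.
disk_raster <- function(W = 101, H = W, r = 20,
                        cx = (W - 1) / 2, cy = (H - 1) / 2,
                        tone = c(128L, 128L, 128L)) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  raster <- array(0L, c(H, W, 3))
  for (ch in 1:3) raster[, , ch][inside] <- tone[ch]
  raster
}

# Uniform-tone raster.
flat_raster <- function(W = 8, H = 8, tone = c(200L, 200L, 200L)) {
  array(rep(as.integer(tone), each = H * W), c(H, W, 3))
}

# Minimal calibrated stack around a list of rasters (pixel 0.02 mm).
raster_stack <- function(rasters, pixel = 0.02, d_s = 0.05,
                         excluded = rep(FALSE, length(rasters))) {
  H <- dim(rasters[[1]])[1]; W <- dim(rasters[[1]])[2]
  sections <- lapply(seq_along(rasters), function(k)
    section_image(rasters[[k]], index = k - 1L, excluded = excluded[k]))
  section_stack(sections, L_w = W * pixel, H_w = H * pixel,
                n_x = W, n_y = H, d_s = d_s)
}

# Hand-built radial contour on a uniform m-angle grid.
make_contour <- function(dist, hit = rep(TRUE, length(dist))) {
  m <- length(dist)
  structure(list(angles = (seq_len(m) - 1L) * (360 / m),
                 dist = dist, hit = hit, m = m), class = "radial_contour")
}
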