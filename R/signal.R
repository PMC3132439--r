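#' Isolate blue-dominant chromogenic signal
#'
#' Flags every tissue voxel whose blue channel exceeds both other channels by
#' at least the margin `delta` (raw 8-bit units):
#' `non-black AND B >= R + delta AND B >= G + delta`. This picks out X-Gal
#' type staining, whose blue tone always rises above the grey tonality of the
#' surrounding tissue; grey voxels (`R = G = B`) are never flagged for any
#' `delta > 0`. Masks are monotone in `delta`: a larger margin can only
#' shrink the mask.
#'
#' @param volume a `voxel_volume`.
#' @param delta non-negative dominance margin in intensity units (0..255).
#' @return A `signal_mask`: logical grid `[H, W, nz]`, the `delta` used, and
#'   the tissue voxel count of the source volume.
#' @export
isolate_signal <- function(volume, delta) {
  if (delta < 0) stopf("delta must be >= 0")
  tis <- volume_tissue_array(volume)
  B <- volume_channel(volume, 3)
  mask <- tis & (B >= volume_channel(volume, 1) + delta) &
                (B >= volume_channel(volume, 2) + delta)
  structure(list(mask = mask, delta = delta, tissue_count = sum(tis)),
            class = "signal_mask")
}

#' Per-section blue-dominance mask (QC before assembly)
#'
#' Same dominance rule as [isolate_signal()], applied to a single section.
#'
#' @param image a [section_image()].
#' @param delta non-negative dominance margin.
#' @return Logical `H x W` matrix.
#' @export
isolate_signal_section <- function(image, delta) {
  if (delta < 0) stopf("delta must be >= 0")
  tissue_mask(image$raster) &
    (image$raster[, , 3] >= image$raster[, , 1] + delta) &
    (image$raster[, , 3] >= image$raster[, , 2] + delta)
}

#' Summarize an isolated signal in physical units
#'
#' Reports voxel count, signal volume (mm^3), the fraction of tissue volume
#' occupied, the signal centroid and bounding box in mm (voxel-centre
#' convention: voxel `(i, j, k)` is centred at `((i+1/2) X_rel, (j+1/2)
#' Y_rel, (k+1/2) Z_rel)`), and — when a reference point such as an injection
#' site is given — the min/mean/max Euclidean distance from the reference to
#' the signal voxels.
#'
#' @param mask a `signal_mask`.
#' @param dims the `voxel_dims` of the volume the mask came from.
#' @param reference_point optional `c(x, y, z)` position in mm.
#' @return A list report; with an empty mask, `count` is 0 and distance and
#'   geometry entries are `NA` with `distances_defined = FALSE`.
#' @export
signal_stats <- function(mask, dims, reference_point = NULL) {
  vox <- dims$x * dims$y * dims$z
  idx <- which(mask$mask, arr.ind = TRUE)
  count <- nrow(idx)
  rep <- list(count = count,
              volume_mm3 = count * vox,
              tissue_fraction = if (mask$tissue_count > 0)
                count / mask$tissue_count else NA_real_,
              delta = mask$delta)
  if (count == 0L) {
    rep$centroid_mm <- rep(NA_real_, 3)
    rep$bbox_mm <- NULL
    rep$distances_defined <- FALSE
    return(rep)
  }
  # arr.ind columns: row (y), col (x), slice (z); convert to 0-based x,y,z
  pts <- cbind(x = (idx[, 2] - 0.5) * dims$x,
               y = (idx[, 1] - 0.5) * dims$y,
               z = (idx[, 3] - 0.5) * dims$z)
  rep$centroid_mm <- colMeans(pts)
  rep$bbox_mm <- rbind(min = c((min(idx[, 2]) - 1) * dims$x,
                               (min(idx[, 1]) - 1) * dims$y,
                               (min(idx[, 3]) - 1) * dims$z),
                       max = c(max(idx[, 2]) * dims$x,
                               max(idx[, 1]) * dims$y,
                               max(idx[, 3]) * dims$z))
  rep$distances_defined <- !is.null(reference_point)
  if (!is.null(reference_point)) {
    dd <- sqrt((pts[, 1] - reference_point[1])^2 +
               (pts[, 2] - reference_point[2])^2 +
               (pts[, 3] - reference_point[3])^2)
    rep$distance_mm <- c(min = min(dd), mean = mean(dd), max = max(dd))
  }
  rep
}

#' Recolour signal voxels in a volume
#'
#' Returns a copy of the volume with every masked voxel set to `color`
#' (default pure red, the conventional overlay for blue X-Gal signal);
#' all other voxels are unchanged.
#'
#' @param volume a `voxel_volume`.
#' @param mask a `signal_mask` with matching dimensions.
#' @param color length-3 RGB vector in 0..255.
#' @return The recoloured `voxel_volume`.
#' @export
overlay_signal <- function(volume, mask, color = c(255L, 0L, 0L)) {
  d <- dim(volume$grid)
  if (!identical(dim(mask$mask), d[c(1, 2, 4)]))
    stopf("mask and volume dimensions differ")
  color <- as.integer(color)
  for (ch in 1:3) {
    plane <- volume_channel(volume, ch)
    plane[mask$mask] <- color[ch]
    volume$grid[, , ch, ] <- plane
  }
  volume
}
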