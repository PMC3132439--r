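#' Physical voxel dimensions of a stack
#'
#' In-plane voxel size comes from the calibration proportion
#' `X_rel = Y_rel = L_w / n_x = H_w / n_y` (square pixels enforced to 1e-6
#' relative); the voxel depth is the inter-section spacing, `Z_rel = d_s` mm.
#'
#' @param stack a [section_stack()].
#' @return A `voxel_dims` object with fields `x`, `y`, `z` (mm).
#' @export
compute_voxel_dims <- function(stack) {
  px <- stack$calibration$L_w / stack$calibration$n_x
  py <- stack$calibration$H_w / stack$calibration$n_y
  if (abs(px - py) > 1e-6 * max(px, py))
    stopf("non-square pixels: L_w/n_x = %g differs from H_w/n_y = %g", px, py)
  structure(list(x = px, y = px, z = stack$d_s), class = "voxel_dims")
}

#' @export
print.voxel_dims <- function(x, ...) {
  cat(sprintf("<voxel_dims> %.6g x %.6g x %.6g mm\n", x$x, x$y, x$z))
  invisible(x)
}

#' Assemble a stack into a calibrated voxel volume
#'
#' One z-slab per stack position, in order, with no inter-slab interpolation.
#' Positions holding an excluded section are filled from the nearest retained
#' section (ties go to the earlier one), so the z-axis stays physically
#' uniform and the loss from discarded sections is minimal.
#'
#' @param stack a cleaned, registered [section_stack()] with at least one
#'   retained section.
#' @return A `voxel_volume`: RGB grid `[H, W, 3, nz]`, `dims` (a
#'   `voxel_dims`), and `source_index`, the section index that filled each
#'   slab.
#' @export
assemble_volume <- function(stack) {
  dims <- compute_voxel_dims(stack)
  excl <- stack_excluded(stack)
  retained <- which(!excl)
  if (length(retained) == 0L) stopf("all sections are excluded")
  n <- length(stack$sections)
  d <- dim(stack$sections[[1]]$raster)
  grid <- array(0L, c(d[1], d[2], 3L, n))
  source_index <- integer(n)
  for (k in seq_len(n)) {
    src <- if (excl[k]) retained[which.min(abs(retained - k))] else k
    grid[, , , k] <- stack$sections[[src]]$raster
    source_index[k] <- stack$sections[[src]]$index
  }
  structure(list(grid = grid, dims = dims, source_index = source_index),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.6g x %.6g x %.6g mm each\n",
              d[2], d[1], d[4], x$dims$x, x$dims$y, x$dims$z))
  invisible(x)
}

# Region = list(x = c(x0, x1), y = ..., z = ...), 0-based inclusive bounds.
check_region <- function(volume, region) {
  d <- dim(volume$grid)
  if (is.null(region))
    return(list(x = c(0L, d[2] - 1L), y = c(0L, d[1] - 1L),
                z = c(0L, d[4] - 1L)))
  lim <- c(x = d[2], y = d[1], z = d[4])
  for (ax in c("x", "y", "z")) {
    r <- region[[ax]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stopf("region$%s must be c(lo, hi) with lo <= hi", ax)
    if (r[1] < 0 || r[2] >= lim[[ax]])
      stopf("region$%s = [%g, %g] lies outside the grid (0..%d)",
            ax, r[1], r[2], lim[[ax]] - 1L)
  }
  region
}

# Channel plane as an [H, W, nz] array (guarding the nz == 1 drop).
volume_channel <- function(volume, ch) {
  d <- dim(volume$grid)
  array(volume$grid[, , ch, , drop = FALSE], d[c(1, 2, 4)])
}

volume_tissue_array <- function(volume) {
  volume_channel(volume, 1) != 0L | volume_channel(volume, 2) != 0L |
    volume_channel(volume, 3) != 0L
}

#' Measure tissue volume
#'
#' Counts every non-black voxel (each voxel representing tissue) in the
#' region and multiplies by the physical voxel volume
#' `X_rel * Y_rel * Z_rel`.
#'
#' @param volume a `voxel_volume`.
#' @param region optional box `list(x = c(x0,x1), y = c(y0,y1), z = c(z0,z1))`
#'   in 0-based inclusive voxel indices; default whole grid.
#' @return Tissue volume in mm^3.
#' @export
measure_volume <- function(volume, region = NULL) {
  region <- check_region(volume, region)
  tis <- volume_tissue_array(volume)
  sub <- tis[(region$y[1] + 1):(region$y[2] + 1),
             (region$x[1] + 1):(region$x[2] + 1),
             (region$z[1] + 1):(region$z[2] + 1), drop = FALSE]
  sum(sub) * volume$dims$x * volume$dims$y * volume$dims$z
}

#' Measure enclosed cavity volume
#'
#' Measures background voxels not connected to the exterior — e.g. ventricle
#' chambers inside a heart reconstruction. Connectivity is evaluated slab by
#' slab: background (black) pixels are flood-filled from the frame border
#' with 4-neighbour connectivity; the black pixels the flood cannot reach are
#' enclosed cavity, and the per-slab cavities are stacked.
#'
#' @inheritParams measure_volume
#' @return Cavity volume in mm^3.
#' @export
measure_cavity_volume <- function(volume, region = NULL) {
  region <- check_region(volume, region)
  tis <- volume_tissue_array(volume)
  count <- 0L
  for (k in (region$z[1] + 1):(region$z[2] + 1)) {
    open <- !tis[, , k]
    reach <- cpp_flood_from_border(open)
    cav <- open & !reach
    count <- count + sum(cav[(region$y[1] + 1):(region$y[2] + 1),
                             (region$x[1] + 1):(region$x[2] + 1)])
  }
  count * volume$dims$x * volume$dims$y * volume$dims$z
}

#' Export a voxel volume
#'
#' `"mhd"` writes a MetaImage pair (plain-text `.mhd` header plus `.raw`
#' block, `MET_UCHAR`, 3 interleaved channels, x fastest) readable by common
#' volume viewers; `"nifti"` writes a NIfTI-1 greyscale (Rec. 601 luminance)
#' volume via RNifti; `"raw"` writes the bare interleaved block plus a JSON
#' sidecar with dimensions and spacing. `ElementSpacing`/`pixdim` carry
#' `(X_rel, Y_rel, Z_rel)` in mm, so anisotropic stacks (e.g. 15-micron
#' sections stained every 60 microns) open with their true physical extent.
#'
#' @param volume a `voxel_volume`.
#' @param path output path without extension.
#' @param format `"mhd"`, `"nifti"` or `"raw"`.
#' @return The header/primary file path, invisibly.
#' @export
export_volume <- function(volume, path, format = c("mhd", "nifti", "raw")) {
  format <- match.arg(format)
  d <- dim(volume$grid)
  # interleave channels per voxel, x fastest, then y, then z
  blob <- as.raw(aperm(volume$grid, c(3, 2, 1, 4)))
  spacing <- c(volume$dims$x, volume$dims$y, volume$dims$z)
  if (format == "mhd") {
    rawfile <- paste0(basename(path), ".raw")
    header <- c("ObjectType = Image",
                "NDims = 3",
                "BinaryData = True",
                "BinaryDataByteOrderMSB = False",
                "CompressedData = False",
                sprintf("DimSize = %d %d %d", d[2], d[1], d[4]),
                sprintf("ElementSpacing = %.9g %.9g %.9g",
                        spacing[1], spacing[2], spacing[3]),
                "ElementNumberOfChannels = 3",
                "ElementType = MET_UCHAR",
                sprintf("ElementDataFile = %s", rawfile))
    writeLines(header, paste0(path, ".mhd"))
    writeBin(blob, file.path(dirname(path), rawfile))
    return(invisible(paste0(path, ".mhd")))
  }
  if (format == "nifti") {
    lum <- round(0.299 * volume$grid[, , 1, ] + 0.587 * volume$grid[, , 2, ] +
                 0.114 * volume$grid[, , 3, ])
    arr <- aperm(array(as.integer(lum), c(d[1], d[2], d[4])), c(2, 1, 3))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    out <- paste0(path, ".nii.gz")
    RNifti::writeNifti(img, out)
    return(invisible(out))
  }
  writeBin(blob, paste0(path, ".raw"))
  jsonlite::write_json(list(dim = c(d[2], d[1], d[4]), channels = 3L,
                            spacing = spacing, order = "cxyz"),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, ".raw"))
}

#' Import a MetaImage volume
#'
#' Reads back a `MET_UCHAR` MetaImage written by [export_volume()] (3-channel
#' or greyscale, uncompressed, little-endian).
#'
#' @param path path to the `.mhd` header.
#' @return A `voxel_volume`.
#' @export
import_mhd <- function(path) {
  if (!file.exists(path)) stopf("header not found: %s", path)
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) default else vals[i]
  }
  if (!identical(get("ElementType"), "MET_UCHAR"))
    stopf("only MET_UCHAR volumes are supported")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  nchan <- as.integer(get("ElementNumberOfChannels", "1"))
  rawfile <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims) * nchan
  blob <- readBin(rawfile, "raw", n)
  if (length(blob) != n) stopf("raw block is truncated: %s", rawfile)
  v <- as.integer(blob)
  if (nchan == 1L) v <- rep(v, each = 1L)
  arr <- array(v, c(nchan, dims[1], dims[2], dims[3]))
  if (nchan == 1L) arr <- arr[c(1, 1, 1), , , , drop = FALSE]
  grid <- aperm(arr, c(3, 2, 1, 4))
  structure(list(grid = grid,
                 dims = structure(list(x = spacing[1], y = spacing[2],
                                       z = spacing[3]), class = "voxel_dims"),
                 source_index = seq_len(dims[3]) - 1L),
            class = "voxel_volume")
}
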