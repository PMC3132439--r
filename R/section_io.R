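#' Create a section image
#'
#' One serial-section raster together with its position in the stack and an
#' exclusion flag. Heavily damaged sections are flagged `excluded` rather
#' than dropped, so the stack keeps a physically uniform z-axis; downstream
#' stages skip excluded sections and the reconstruction fills their slab from
#' the nearest retained neighbour.
#'
#' @param raster `H x W x 3` array of 8-bit RGB values (0..255).
#' @param index 0-based position of the section in the stack.
#' @param excluded logical; `TRUE` marks the section as excluded from
#'   registration, contour correction and direct assembly.
#' @return A `section_image` object.
#' @export
section_image <- function(raster, index = 0L, excluded = FALSE) {
  raster <- as_raster_array(raster)
  structure(list(raster = raster,
                 index = as.integer(index),
                 excluded = isTRUE(excluded)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<section_image> index %d, %d x %d px%s\n",
              x$index, d[2], d[1], if (x$excluded) ", EXCLUDED" else ""))
  invisible(x)
}

#' Create a section stack
#'
#' An ordered stack of section images plus the physical calibration needed to
#' turn pixel counts into millimetres: a known tissue length `L_w` spanning
#' `n_x` pixels (and `H_w` over `n_y`), and the inter-section spacing `d_s`.
#' Pixels must be square: `L_w/n_x` and `H_w/n_y` must agree to 1e-6
#' relative. The in-plane pixel size is `L_w/n_x` mm; the slab depth is `d_s`
#' mm (for a brain series stained every fourth 15-micron section,
#' `d_s = 0.06`).
#'
#' @param sections list of [section_image()] objects with strictly increasing
#'   indices and identical dimensions.
#' @param L_w,H_w physical extents (mm) of the calibrated tissue span.
#' @param n_x,n_y pixel counts of the same span.
#' @param d_s inter-section spacing (mm), > 0.
#' @param provenance character vector logging the stages already applied.
#' @return A `section_stack` object.
#' @export
section_stack <- function(sections, L_w, H_w, n_x, n_y, d_s,
                          provenance = character()) {
  if (length(sections) < 1L) stopf("a stack needs at least one section")
  if (!all(vapply(sections, inherits, logical(1), "section_image")))
    stopf("sections must be section_image objects")
  dims <- vapply(sections, function(s) dim(s$raster)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("section %d has dimensions %dx%d, expected %dx%d",
          sections[[which(dims[1, ] != dims[1, 1] |
                          dims[2, ] != dims[2, 1])[1]]]$index,
          dims[2, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
          dims[1, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
          dims[2, 1], dims[1, 1])
  idx <- vapply(sections, `[[`, integer(1), "index")
  if (any(diff(idx) <= 0L)) stopf("section indices must be strictly increasing")
  if (d_s <= 0) stopf("d_s must be > 0")
  if (L_w <= 0 || H_w <= 0 || n_x <= 0 || n_y <= 0)
    stopf("calibration values must be > 0")
  px <- L_w / n_x
  py <- H_w / n_y
  if (abs(px - py) > 1e-6 * max(px, py))
    stopf("non-square pixels: L_w/n_x = %g differs from H_w/n_y = %g", px, py)
  structure(list(sections = sections,
                 calibration = list(L_w = L_w, H_w = H_w,
                                    n_x = as.integer(n_x),
                                    n_y = as.integer(n_y)),
                 d_s = d_s,
                 provenance = as.character(provenance)),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]]$raster)
  cat(sprintf(paste0("<section_stack> %d sections (%d excluded), %d x %d px, ",
                     "pixel %.6g mm, d_s %.6g mm\n"),
              length(x$sections), sum(stack_excluded(x)), d[2], d[1],
              pixel_size(x), x$d_s))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' In-plane pixel size of a stack (mm per pixel)
#'
#' @param stack a `section_stack`.
#' @return `L_w / n_x` in mm/px; invariant under every pipeline stage.
#' @export
pixel_size <- function(stack) {
  stack$calibration$L_w / stack$calibration$n_x
}

stack_excluded <- function(stack) {
  vapply(stack$sections, `[[`, logical(1), "excluded")
}

add_provenance <- function(stack, entry) {
  stack$provenance <- c(stack$provenance, entry)
  stack
}

# ---- raster file IO --------------------------------------------------------

# Convert a [0,1] double array from png/tiff readers to 8-bit RGB.
normalize_raster <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  nc <- dim(arr)[3]
  if (nc == 1L) arr <- arr[, , c(1, 1, 1), drop = FALSE]
  else if (nc == 2L) arr <- arr[, , c(1, 1, 1), drop = FALSE]  # grey + alpha
  else if (nc >= 3L) arr <- arr[, , 1:3, drop = FALSE]
  as_raster_array(array(as.integer(round(arr * 255)), dim(arr)))
}

read_raster <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = normalize_raster(png::readPNG(path), path),
         tif = ,
         tiff = normalize_raster(tiff::readTIFF(path), path),
         bmp = read_bmp(path),
         stopf("unsupported image format '%s' (%s)", ext, path))
}

write_raster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(raster / 255, path),
         tif = ,
         tiff = tiff::writeTIFF(raster / 255, path, compression = "none"),
         bmp = write_bmp(raster, path),
         stopf("unsupported image format '%s' (%s)", ext, path))
  invisible(path)
}

# Minimal uncompressed 24-bit BMP reader (bottom-up, BI_RGB). Covers the
# classic Windows bitmaps produced by older acquisition software.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stopf("%s is not a BMP file", path)
  readBin(con, "integer", 2, size = 4, endian = "little")   # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdrsize <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdrsize < 40L) stopf("%s: unsupported BMP header", path)
  W <- readBin(con, "integer", 1, size = 4, endian = "little")
  H <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")   # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  comp <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (bpp != 24L || comp != 0L)
    stopf("%s: only uncompressed 24-bit BMP is supported", path)
  if (H < 0L) stopf("%s: top-down BMP not supported", path)
  seek(con, offset)
  rowbytes <- ((W * 3 + 3) %/% 4) * 4
  px <- readBin(con, "integer", rowbytes * H, size = 1, signed = FALSE)
  rows <- matrix(px, nrow = rowbytes)[seq_len(W * 3), , drop = FALSE]
  # rows are bottom-up, pixels B,G,R
  arr <- array(0L, c(H, W, 3))
  b <- matrix(rows[seq(1, W * 3, by = 3), ], nrow = W)
  g <- matrix(rows[seq(2, W * 3, by = 3), ], nrow = W)
  r <- matrix(rows[seq(3, W * 3, by = 3), ], nrow = W)
  arr[, , 1] <- t(r)[H:1, , drop = FALSE]
  arr[, , 2] <- t(g)[H:1, , drop = FALSE]
  arr[, , 3] <- t(b)[H:1, , drop = FALSE]
  as_raster_array(arr)
}

write_bmp <- function(raster, path) {
  raster <- as_raster_array(raster)
  H <- dim(raster)[1]; W <- dim(raster)[2]
  rowbytes <- ((W * 3 + 3) %/% 4) * 4
  datasize <- rowbytes * H
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(c(54 + datasize, 0, 54)), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(c(W, H)), con, size = 4, endian = "little")
  writeBin(c(1L, 24L), con, size = 2, endian = "little")
  writeBin(as.integer(c(0, datasize, 2835, 2835, 0, 0)), con,
           size = 4, endian = "little")
  rows <- matrix(0L, nrow = rowbytes, ncol = H)
  flip <- H:1
  rows[seq(1, W * 3, by = 3), ] <- t(raster[flip, , 3])
  rows[seq(2, W * 3, by = 3), ] <- t(raster[flip, , 2])
  rows[seq(3, W * 3, by = 3), ] <- t(raster[flip, , 1])
  writeBin(as.raw(as.vector(rows)), con)
  invisible(path)
}

# ---- manifest IO -----------------------------------------------------------

read_manifest_file <- function(path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Load a section stack from a manifest
#'
#' The manifest (YAML, or JSON by extension) lists the image files in stack
#' order together with the calibration, spacing, exclusions and provenance:
#' ```yaml
#' images: [section_000.png, section_001.png]
#' calibration: {L_w: 5.0, H_w: 5.0, n_x: 500, n_y: 500}
#' d_s: 0.06
#' excluded: [3]        # 0-based stack indices, optional
#' provenance: []       # optional
#' ```
#' Image paths are resolved relative to the manifest's directory. PNG, TIFF
#' and uncompressed 24-bit BMP are accepted; greyscale and 16-bit inputs are
#' converted to 8-bit RGB. Excluded sections are loaded and flagged, never
#' dropped.
#'
#' @param manifest_path path to the manifest file.
#' @return A [section_stack()].
#' @export
load_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  m <- read_manifest_file(manifest_path)
  for (key in c("images", "calibration", "d_s"))
    if (is.null(m[[key]])) stopf("manifest is missing '%s'", key)
  if (length(m$images) < 1L) stopf("manifest lists no images")
  base <- dirname(manifest_path)
  excluded <- as.integer(m$excluded %||% integer())
  sections <- vector("list", length(m$images))
  ref_dim <- NULL
  for (k in seq_along(m$images)) {
    path <- file.path(base, m$images[[k]])
    raster <- read_raster(path)
    if (is.null(ref_dim)) ref_dim <- dim(raster)[1:2]
    else if (!identical(dim(raster)[1:2], ref_dim))
      stopf("section %d (%s) is %dx%d px, expected %dx%d", k - 1L,
            m$images[[k]], dim(raster)[2], dim(raster)[1],
            ref_dim[2], ref_dim[1])
    sections[[k]] <- section_image(raster, index = k - 1L,
                                   excluded = (k - 1L) %in% excluded)
  }
  cal <- m$calibration
  section_stack(sections,
                L_w = cal$L_w, H_w = cal$H_w, n_x = cal$n_x, n_y = cal$n_y,
                d_s = m$d_s,
                provenance = as.character(m$provenance %||% character()))
}

#' Save a section stack
#'
#' Writes every section losslessly (PNG by default) plus a YAML manifest
#' recording calibration, spacing, exclusions and the provenance log.
#' Excluded sections are written like any other and marked in the manifest.
#'
#' @param stack a [section_stack()].
#' @param out_dir output directory (created if missing).
#' @param format one of `"png"`, `"tiff"`, `"bmp"`.
#' @return The manifest path, invisibly.
#' @export
save_stack <- function(stack, out_dir, format = c("png", "tiff", "bmp")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0L) stopf("directory not writable: %s", out_dir)
  files <- sprintf("section_%04d.%s",
                   vapply(stack$sections, `[[`, integer(1), "index"), format)
  for (k in seq_along(stack$sections))
    write_raster(stack$sections[[k]]$raster, file.path(out_dir, files[k]))
  manifest <- list(
    images = as.list(files),
    calibration = stack$calibration,
    d_s = stack$d_s,
    excluded = as.list(vapply(stack$sections, `[[`, integer(1),
                              "index")[stack_excluded(stack)]),
    provenance = as.list(stack$provenance))
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
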