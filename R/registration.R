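#' Centroid of the tissue pixels of a section
#'
#' Unweighted mean of the 0-based `(x, y)` coordinates of all non-black
#' pixels — the "barycentre" used to centre each section. Intensity plays no
#' role; every tissue pixel counts once.
#'
#' @param image a [section_image()] (cleaned, so tissue = non-black).
#' @return Numeric `c(x, y)` centroid in pixels.
#' @export
compute_centroid <- function(image) {
  mask <- tissue_mask(image$raster)
  if (!any(mask)) stopf("empty section: no non-black pixel")
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' Centre a section on its frame
#'
#' Translates the tissue by the integer shift `round(centre - centroid)` so
#' the tissue barycentre lands on the frame centre `((W-1)/2, (H-1)/2)`.
#' Vacated pixels are exact black; the non-black pixel count is unchanged.
#' Tissue that would leave the frame raises an error (pad the images and
#' retry).
#'
#' @param image a [section_image()] with at least one non-black pixel.
#' @return `list(image = centred section_image, offset = centroid_offset)`
#'   where `offset` holds the measured `centroid`, the frame `center` and the
#'   integer `shift = c(dx, dy)` that was applied.
#' @export
center_section <- function(image) {
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  ctr <- frame_center(W, H)
  centroid <- compute_centroid(image)
  shift <- as.integer(round(ctr - centroid))
  out <- image
  if (any(shift != 0L)) {
    mask <- tissue_mask(image$raster)
    rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
    if (min(rows) + shift[2] < 1L || max(rows) + shift[2] > H ||
        min(cols) + shift[1] < 1L || max(cols) + shift[1] > W)
      stopf("centring would move tissue outside the frame; pad the images")
    raster <- array(0L, dim(image$raster))
    src_y <- (max(1L, 1L - shift[2])):(min(H, H - shift[2]))
    src_x <- (max(1L, 1L - shift[1])):(min(W, W - shift[1]))
    raster[src_y + shift[2], src_x + shift[1], ] <-
      image$raster[src_y, src_x, , drop = FALSE]
    out$raster <- raster
  }
  offset <- structure(list(centroid = centroid, center = ctr,
                           shift = shift), class = "centroid_offset")
  list(image = out, offset = offset)
}

# Tie-break among grid angles with equal metric: smallest |angle| (wrapped to
# (-180, 180]) wins; between +theta and -theta the positive angle wins.
pick_angle <- function(angles, d) {
  dmin <- min(d)
  cand <- which(d == dmin)
  signed <- wrap_angle(angles[cand])
  cand[order(abs(signed), -signed)][1]
}

#' Orient a section against a reference by exhaustive rotation search
#'
#' Rotates the section through the full 360 degrees on a fixed angular grid
#' and, for each candidate angle, computes the intensity-difference metric
#' `d(theta)` between the rotated section and the reference: the sum over all
#' pixels of the absolute difference of Rec. 601 luminances (`"l1"`, the
#' default) or of squared differences (`"ssd"`). The returned rotation is the
#' grid angle with the smallest `d`; exact ties go to the smallest wrapped
#' angle, positive before negative. Rotation is about the frame centre with
#' nearest-neighbour resampling, so centring is preserved and background
#' stays exact black.
#'
#' @param image,reference centred [section_image()]s of identical dimensions.
#' @param angular_step grid step in degrees; must divide 360. The default 1
#'   degree gives 360 candidate orientations.
#' @param metric `"l1"` or `"ssd"`.
#' @return `list(image = rotated section_image, result = rotation_result)`;
#'   `result` holds `angle` (deg), `d` at that angle, and the full `curve`
#'   data frame (`theta`, `d`) over the grid.
#' @export
align_rotation <- function(image, reference, angular_step = 1,
                           metric = c("l1", "ssd")) {
  metric <- match.arg(metric)
  if (!identical(dim(image$raster), dim(reference$raster)))
    stopf("image and reference dimensions differ")
  if (angular_step <= 0 || (360 %% angular_step) != 0)
    stopf("angular_step must be a positive divisor of 360")
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  ctr <- frame_center(W, H)
  angles <- seq(0, 360 - angular_step, by = angular_step)
  d <- cpp_rotation_curve(luminance(image$raster), luminance(reference$raster),
                          angles, ctr[1], ctr[2],
                          if (metric == "ssd") 1L else 0L)
  best <- pick_angle(angles, d)
  out <- image
  out$raster <- cpp_rotate_raster(image$raster, angles[best], ctr[1], ctr[2])
  result <- structure(list(angle = angles[best], d = d[best],
                           curve = data.frame(theta = angles, d = d)),
                      class = "rotation_result")
  list(image = out, result = result)
}

#' Rotate a section about the frame centre
#'
#' Nearest-neighbour inverse-mapping rotation; pixels mapping outside the
#' frame become exact black. Positive angles rotate `+x` toward `+y`.
#'
#' @param image a [section_image()].
#' @param theta rotation angle in degrees.
#' @return The rotated `section_image`.
#' @export
rotate_section <- function(image, theta) {
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  ctr <- frame_center(W, H)
  out <- image
  out$raster <- cpp_rotate_raster(image$raster, theta, ctr[1], ctr[2])
  out
}

#' Register a whole stack: centre every section, orient chain-wise
#'
#' Each retained (non-excluded) section is centred with [center_section()],
#' then oriented with [align_rotation()] against the nearest preceding
#' retained section in its already-registered state. The first retained
#' section is the unrotated anchor. Excluded sections are left untouched and
#' skipped by the chain.
#'
#' @param stack a cleaned [section_stack()] with at least one retained
#'   section.
#' @param angular_step,metric passed to [align_rotation()].
#' @return `list(stack = registered section_stack, diagnostics = data.frame)`
#'   with one diagnostics row per retained section: `index`, centring shift
#'   `dx`, `dy`, rotation `theta`, metric value `d` (NA for the anchor), and
#'   `curves`, a named list of the full metric curves.
#' @export
register_stack <- function(stack, angular_step = 1, metric = c("l1", "ssd")) {
  metric <- match.arg(metric)
  retained <- which(!stack_excluded(stack))
  if (length(retained) == 0L) stopf("no retained sections to register")
  diag <- data.frame(index = integer(), dx = integer(), dy = integer(),
                     theta = numeric(), d = numeric())
  curves <- list()
  prev <- NULL
  for (k in retained) {
    cen <- center_section(stack$sections[[k]])
    if (is.null(prev)) {
      stack$sections[[k]] <- cen$image
      diag[nrow(diag) + 1L, ] <- list(cen$image$index,
                                      cen$offset$shift[1], cen$offset$shift[2],
                                      0, NA_real_)
    } else {
      ali <- align_rotation(cen$image, prev, angular_step, metric)
      stack$sections[[k]] <- ali$image
      diag[nrow(diag) + 1L, ] <- list(ali$image$index,
                                      cen$offset$shift[1], cen$offset$shift[2],
                                      ali$result$angle, ali$result$d)
      curves[[as.character(ali$image$index)]] <- ali$result$curve
    }
    prev <- stack$sections[[k]]
  }
  list(stack = add_provenance(stack, "register"),
       diagnostics = diag, curves = curves)
}

#' Score registration against phantom ground truth
#'
#' Compares [register_stack()] diagnostics with the transforms a phantom
#' recorded. Translation is scored absolutely: the applied centring shift is
#' compared with `round(frame centre - true tissue centroid)` of the
#' perturbed slice. Rotation is scored per link: for each section the
#' residual orientation `true theta + applied theta` is differenced against
#' the residual of the section it was aligned to, because chain alignment on
#' a discrete angular grid controls each link's accuracy while absolute
#' orientation performs a slow quantization walk along the chain. The anchor
#' section's rotation error is 0 by construction.
#'
#' @param diagnostics the diagnostics data frame from [register_stack()].
#' @param truth the `phantom_truth` of the same stack.
#' @param stack the phantom stack (for the frame centre).
#' @return Data frame with `index`, `trans_err_px` (Chebyshev) and
#'   `rot_err_deg` per retained section.
#' @export
evaluate_registration <- function(diagnostics, truth, stack) {
  d <- dim(stack$sections[[1]]$raster)
  ctr <- frame_center(d[2], d[1])
  tr <- truth$slices[match(diagnostics$index, truth$slices$index), ]
  trans_err <- pmax(abs(diagnostics$dx - round(ctr[1] - tr$centroid_x)),
                    abs(diagnostics$dy - round(ctr[2] - tr$centroid_y)))
  residual <- tr$theta + diagnostics$theta
  rot_err <- c(0, abs(wrap_angle(diff(residual))))
  data.frame(index = diagnostics$index,
             trans_err_px = trans_err, rot_err_deg = rot_err)
}
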