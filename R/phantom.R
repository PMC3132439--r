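#' Specify a phantom shape
#'
#' A solid 3D shape of known geometry that stands in for the sectioned organ.
#' Supported kinds:
#' * `"sphere"` — `radius` (mm);
#' * `"ellipsoid"` — semi-axes `a`, `b` (in-plane) and `c` (along z), mm;
#' * `"cylinder"` — `radius` and `height` (axis along z), with an optional
#'   `bore_radius` to drill enclosed channels parallel to the axis,
#'   displaced `bore_offset` mm along x (vectors drill several bores).
#'   Off-axis bores give every cross-section a rotationally asymmetric
#'   landmark, making rotation recovery well-posed at every slice; two
#'   unequal bores with balanced first moments
#'   (`sum(bore_radius^2 * bore_offset) == 0`) additionally keep the tissue
#'   barycentre on the cylinder axis, so barycentric centring and rotation
#'   about the frame centre commute;
#' * `"two-lobed-union"` — union of two spheres `radius` and `radius2` whose
#'   centres sit `separation` mm apart along x; unequal lobes give a shape
#'   with no rotational symmetry, which makes rotation recovery well-posed.
#'
#' @param kind shape kind (see above).
#' @param radius,radius2,a,b,c,height,separation,bore_radius,bore_offset size
#'   parameters in mm, all `> 0` where used; `bore_radius`/`bore_offset` are
#'   equal-length vectors (possibly length 0 or scalar 0 for no bore) and
#'   every bore must lie strictly inside the cylinder and not overlap
#'   another.
#' @param tissue_tone,background_tone RGB triples; tissue must not be exact
#'   black and must differ from the background. Defaults: mid grey tissue on
#'   a pale slide-like background.
#' @return A `shape_spec`.
#' @export
shape_spec <- function(kind = c("sphere", "ellipsoid", "cylinder",
                                "two-lobed-union"),
                       radius = NULL, radius2 = NULL, a = NULL, b = NULL,
                       c = NULL, height = NULL, separation = NULL,
                       bore_radius = 0, bore_offset = 0,
                       tissue_tone = base::c(128L, 128L, 128L),
                       background_tone = base::c(230L, 228L, 220L)) {
  kind <- match.arg(kind)
  need <- function(val, name) {
    if (is.null(val) || val <= 0) stopf("%s requires %s > 0", kind, name)
    val
  }
  par <- switch(kind,
    sphere = list(radius = need(radius, "radius")),
    ellipsoid = list(a = need(a, "a"), b = need(b, "b"), c = need(c, "c")),
    cylinder = {
      r <- need(radius, "radius")
      keep <- bore_radius > 0
      bore_radius <- bore_radius[keep]
      bore_offset <- rep_len(bore_offset, length(keep))[keep]
      if (length(bore_radius) != length(bore_offset))
        stopf("bore_radius and bore_offset lengths differ")
      if (any(abs(bore_offset) + bore_radius >= r))
        stopf("every bore must lie strictly inside the cylinder")
      if (length(bore_radius) > 1L) {
        sep <- abs(outer(bore_offset, bore_offset, "-"))
        lim <- outer(bore_radius, bore_radius, "+")
        if (any(sep[lower.tri(sep)] < lim[lower.tri(lim)]))
          stopf("bores overlap")
      }
      list(radius = r, height = need(height, "height"),
           bore_radius = bore_radius, bore_offset = bore_offset)
    },
    `two-lobed-union` = list(radius = need(radius, "radius"),
                             radius2 = need(radius2 %||% radius, "radius2"),
                             separation = need(separation, "separation")))
  tissue_tone <- as.integer(tissue_tone)
  background_tone <- as.integer(background_tone)
  if (all(tissue_tone == 0L)) stopf("tissue tone must not be exact black")
  if (all(tissue_tone == background_tone))
    stopf("tissue tone must differ from background tone")
  # base::c — the semi-axis argument `c` shadows the base function here
  structure(base::c(list(kind = kind), par,
                    list(tissue_tone = tissue_tone,
                         background_tone = background_tone)),
            class = "shape_spec")
}

# z extent (mm) and in-plane half extent (mm) of a shape.
shape_extent <- function(shape) {
  switch(shape$kind,
    sphere = list(z = 2 * shape$radius, half_xy = shape$radius),
    ellipsoid = list(z = 2 * shape$c, half_xy = max(shape$a, shape$b)),
    cylinder = list(z = shape$height, half_xy = shape$radius),
    `two-lobed-union` = list(
      z = 2 * max(shape$radius, shape$radius2),
      half_xy = shape$separation / 2 + max(shape$radius, shape$radius2)))
}

# Membership test: mx, my, dz in mm relative to the shape centre, vectorized
# over mx/my with scalar dz.
shape_member <- function(shape, mx, my, dz) {
  switch(shape$kind,
    sphere = mx^2 + my^2 + dz^2 <= shape$radius^2,
    ellipsoid = (mx / shape$a)^2 + (my / shape$b)^2 +
      (dz / shape$c)^2 <= 1,
    cylinder = {
      inside <- mx^2 + my^2 <= shape$radius^2 & abs(dz) <= shape$height / 2
      for (b in seq_along(shape$bore_radius))
        inside <- inside &
          (mx - shape$bore_offset[b])^2 + my^2 >= shape$bore_radius[b]^2
      inside
    },
    `two-lobed-union` = {
      h <- shape$separation / 2
      (mx + h)^2 + my^2 + dz^2 <= shape$radius^2 |
      (mx - h)^2 + my^2 + dz^2 <= shape$radius2^2
    })
}

# Signed clearance (mm) from a 3D point to the shape boundary (positive
# inside); used to place signal blobs strictly inside the tissue.
shape_clearance <- function(shape, p) {
  switch(shape$kind,
    sphere = shape$radius - sqrt(sum(p^2)),
    ellipsoid = (1 - sqrt((p[1] / shape$a)^2 + (p[2] / shape$b)^2 +
                          (p[3] / shape$c)^2)) * min(shape$a, shape$b, shape$c),
    cylinder = {
      rho <- sqrt(p[1]^2 + p[2]^2)
      cl <- c(shape$radius - rho, shape$height / 2 - abs(p[3]))
      for (b in seq_along(shape$bore_radius))
        cl <- c(cl, sqrt((p[1] - shape$bore_offset[b])^2 + p[2]^2) -
                    shape$bore_radius[b])
      min(cl)
    },
    `two-lobed-union` = {
      h <- shape$separation / 2
      max(shape$radius - sqrt((p[1] + h)^2 + p[2]^2 + p[3]^2),
          shape$radius2 - sqrt((p[1] - h)^2 + p[2]^2 + p[3]^2))
    })
}

#' Closed-form volume of a phantom shape
#'
#' Sphere `4/3 pi r^3`; ellipsoid `4/3 pi a b c`; cylinder
#' `pi (r^2 - r_bore^2) h`; two-lobed union `V1 + V2` minus the standard
#' sphere-sphere lens intersection when the lobes overlap.
#'
#' @param shape a [shape_spec()].
#' @return Volume in mm^3.
#' @export
analytic_volume <- function(shape) {
  if (!inherits(shape, "shape_spec")) stopf("shape must be a shape_spec")
  switch(shape$kind,
    sphere = 4 / 3 * pi * shape$radius^3,
    ellipsoid = 4 / 3 * pi * shape$a * shape$b * shape$c,
    cylinder = pi * (shape$radius^2 - sum(shape$bore_radius^2)) *
      shape$height,
    `two-lobed-union` = {
      r1 <- shape$radius; r2 <- shape$radius2; d <- shape$separation
      v <- 4 / 3 * pi * (r1^3 + r2^3)
      if (d >= r1 + r2) v
      else if (d <= abs(r1 - r2)) 4 / 3 * pi * max(r1, r2)^3
      else v - pi * (r1 + r2 - d)^2 *
        (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
    },
    stopf("unsupported shape kind"))
}

#' Specify phantom perturbations
#'
#' Emulates the inaccuracies of mounting cryostat sections on slides:
#' per-slice random translation and rotation, a sinusoidal radial contour
#' deformation `rho' = rho * (1 + A sin(f alpha + phi))` with a random phase
#' per slice, salt/pepper contamination of the background, bright glare
#' spots, and optional blue signal blobs placed strictly inside the tissue.
#' A fixed `seed` makes the generated stack bit-identical across runs.
#'
#' @param translation_px max absolute per-slice translation (integer pixels,
#'   drawn uniformly per axis).
#' @param rotation_deg max absolute per-slice rotation (degrees, drawn
#'   uniformly, continuous).
#' @param deform_amplitude radial deformation amplitude `A` as a fraction of
#'   the local radius, in `[0, 1)`.
#' @param deform_frequency integer angular frequency `f` (cycles per turn).
#' @param noise_density fraction of background pixels flipped to salt (white)
#'   or pepper (black), in `[0, 1]`.
#' @param glare_count,glare_radius_px number and radius of bright glare spots
#'   drawn on the background.
#' @param signal_count,signal_radius_mm number and radius of spherical blue
#'   signal blobs.
#' @param signal_tone RGB triple of the blobs; blue-dominant by default
#'   (`(40, 40, 120)`: blue exceeds the other channels by 80).
#' @param seed integer RNG seed.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(translation_px = 0L, rotation_deg = 0,
                              deform_amplitude = 0, deform_frequency = 0L,
                              noise_density = 0, glare_count = 0L,
                              glare_radius_px = 3L, signal_count = 0L,
                              signal_radius_mm = 0.3,
                              signal_tone = c(40L, 40L, 120L), seed = 1L) {
  if (deform_amplitude < 0 || deform_amplitude >= 1)
    stopf("deform_amplitude must lie in [0, 1)")
  if (noise_density < 0 || noise_density > 1)
    stopf("noise_density must lie in [0, 1]")
  if (translation_px < 0 || rotation_deg < 0)
    stopf("perturbation ranges must be >= 0")
  structure(list(translation_px = as.integer(translation_px),
                 rotation_deg = rotation_deg,
                 deform_amplitude = deform_amplitude,
                 deform_frequency = as.integer(deform_frequency),
                 noise_density = noise_density,
                 glare_count = as.integer(glare_count),
                 glare_radius_px = as.integer(glare_radius_px),
                 signal_count = as.integer(signal_count),
                 signal_radius_mm = signal_radius_mm,
                 signal_tone = as.integer(signal_tone),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

place_blobs <- function(shape, perturb, pixel_size) {
  n <- perturb$signal_count
  if (n == 0L) return(NULL)
  br <- perturb$signal_radius_mm
  ext <- shape_extent(shape)
  margin <- br + 2 * pixel_size +
    perturb$deform_amplitude * ext$half_xy
  blobs <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(blobs) < n) {
    if ((tries <- tries + 1L) > 20000L)
      stopf("could not place %d signal blobs inside the tissue", n)
    p <- c(runif(1, -ext$half_xy, ext$half_xy),
           runif(1, -ext$half_xy, ext$half_xy),
           runif(1, -ext$z / 2, ext$z / 2))
    if (shape_clearance(shape, p) < margin) next
    if (nrow(blobs) > 0 &&
        any(sqrt(rowSums(sweep(blobs, 2, p)^2)) < 2 * br + pixel_size)) next
    blobs <- rbind(blobs, p)
  }
  blobs
}

#' Generate a synthetic serial-section phantom
#'
#' Slices a solid shape of known geometry at fixed spacing (each slab sampled
#' at its mid-plane, `z = (k + 1/2) d_s`, with no partial-volume rendering),
#' renders each cross-section in the tissue tone on the background tone, and
#' perturbs each slice in the recorded order: rotation about the frame
#' centre, translation, radial contour deformation, then noise (glare spots
#' and salt/pepper). Slices are rendered analytically through the inverse of
#' the composed transform, so the geometry is exact and free of accumulated
#' resampling. The returned truth carries everything needed to score a
#' pipeline: the applied per-slice transforms, the true tissue centroid, the
#' noise-free tissue and signal masks per slice, and the analytic volumes.
#'
#' Slices that intersect no tissue (possible when `n_sections * d_s` exceeds
#' the shape extent) are generated as pure background and flagged excluded.
#'
#' @param shape a [shape_spec()].
#' @param n_sections number of slices; `n_sections * d_s` must cover the
#'   shape's z extent.
#' @param d_s inter-section spacing (mm).
#' @param pixel_size in-plane pixel size (mm/px).
#' @param perturb a [perturbation_spec()].
#' @param frame_px optional frame side length (pixels); default is sized so
#'   the worst-case perturbed slice fits with margin, rounded up to odd so
#'   the frame centre is a pixel.
#' @return `list(stack = section_stack, truth = phantom_truth)`. The truth's
#'   `slices` data frame has one row per section: `index`, applied `dx`,
#'   `dy`, `theta`, deformation phase `phi`, true tissue centroid
#'   (`centroid_x`, `centroid_y`) and tissue pixel `area`.
#' @export
generate_phantom <- function(shape, n_sections, d_s, pixel_size,
                             perturb = perturbation_spec(),
                             frame_px = NULL) {
  if (pixel_size <= 0 || d_s <= 0) stopf("pixel_size and d_s must be > 0")
  ext <- shape_extent(shape)
  if (n_sections * d_s < ext$z - 1e-9)
    stopf("n_sections * d_s = %g mm does not cover the shape extent %g mm",
          n_sections * d_s, ext$z)
  if (is.null(frame_px)) {
    half <- ceiling(ext$half_xy / pixel_size * (1 + perturb$deform_amplitude) +
                    perturb$translation_px + perturb$glare_radius_px) + 4L
    frame_px <- 2L * as.integer(half) + 1L
  }
  W <- H <- as.integer(frame_px)
  ctr <- frame_center(W, H)
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  zc <- n_sections * d_s / 2

  with_seed(perturb$seed, {
    blobs <- place_blobs(shape, perturb, pixel_size)
    thetas <- if (perturb$rotation_deg > 0)
      runif(n_sections, -perturb$rotation_deg, perturb$rotation_deg)
      else numeric(n_sections)
    dxs <- dys <- integer(n_sections)
    if (perturb$translation_px > 0L) {
      span <- -perturb$translation_px:perturb$translation_px
      dxs <- sample(span, n_sections, replace = TRUE)
      dys <- sample(span, n_sections, replace = TRUE)
    }
    phis <- if (perturb$deform_amplitude > 0)
      runif(n_sections, 0, 2 * pi) else numeric(n_sections)

    sections <- vector("list", n_sections)
    tissue_masks <- vector("list", n_sections)
    signal_masks <- vector("list", n_sections)
    slices <- data.frame(index = seq_len(n_sections) - 1L,
                         dx = dxs, dy = dys, theta = thetas, phi = phis,
                         centroid_x = NA_real_, centroid_y = NA_real_,
                         area = NA_integer_)
    for (k in seq_len(n_sections)) {
      dz <- (k - 0.5) * d_s - zc
      # invert the composed perturbation analytically: undo deformation
      # (about the translated centre), then translation, then rotation
      dxp <- X - (ctr[1] + dxs[k]); dyp <- Y - (ctr[2] + dys[k])
      rho <- sqrt(dxp^2 + dyp^2)
      al <- atan2(dyp, dxp)
      A <- perturb$deform_amplitude
      rho_u <- if (A > 0)
        rho / (1 + A * sin(perturb$deform_frequency * al + phis[k]))
        else rho
      vx <- rho_u * cos(al); vy <- rho_u * sin(al)
      th <- thetas[k] * pi / 180
      wx <- cos(th) * vx + sin(th) * vy
      wy <- -sin(th) * vx + cos(th) * vy
      mx <- wx * pixel_size; my <- wy * pixel_size
      inside <- shape_member(shape, mx, my, dz)
      if (any(inside) &&
          (any(inside[1, ]) || any(inside[H, ]) ||
           any(inside[, 1]) || any(inside[, W])))
        stopf("slice %d: tissue exceeds the image frame; enlarge frame_px",
              k - 1L)
      sig <- matrix(FALSE, H, W)
      if (!is.null(blobs)) {
        br2 <- perturb$signal_radius_mm^2
        for (b in seq_len(nrow(blobs)))
          sig <- sig | ((mx - blobs[b, 1])^2 + (my - blobs[b, 2])^2 +
                        (dz - blobs[b, 3])^2 <= br2)
        sig <- sig & inside
      }
      raster <- array(0L, c(H, W, 3))
      for (ch in 1:3) {
        plane <- matrix(shape$background_tone[ch], H, W)
        plane[inside] <- shape$tissue_tone[ch]
        plane[sig] <- perturb$signal_tone[ch]
        raster[, , ch] <- plane
      }
      # noise goes on the background only, so the truth tissue mask is exact
      if (perturb$glare_count > 0L) {
        for (g in seq_len(perturb$glare_count)) {
          gx <- runif(1, 0, W - 1); gy <- runif(1, 0, H - 1)
          spot <- (X - gx)^2 + (Y - gy)^2 <= perturb$glare_radius_px^2 &
                  !inside
          for (ch in 1:3) {
            plane <- raster[, , ch]
            plane[spot] <- c(250L, 250L, 246L)[ch]
            raster[, , ch] <- plane
          }
        }
      }
      if (perturb$noise_density > 0) {
        bg_idx <- which(!inside)
        nnoise <- floor(perturb$noise_density * length(bg_idx))
        if (nnoise > 0L) {
          pick <- sample(bg_idx, nnoise)
          salt <- runif(nnoise) < 0.5
          for (ch in 1:3) {
            plane <- raster[, , ch]
            plane[pick[salt]] <- 255L
            plane[pick[!salt]] <- 0L
            raster[, , ch] <- plane
          }
        }
      }
      empty <- !any(inside)
      sections[[k]] <- section_image(raster, index = k - 1L, excluded = empty)
      tissue_masks[[k]] <- inside
      signal_masks[[k]] <- sig
      slices$area[k] <- sum(inside)
      if (!empty) {
        idx <- which(inside, arr.ind = TRUE)
        slices$centroid_x[k] <- mean(idx[, 2]) - 1
        slices$centroid_y[k] <- mean(idx[, 1]) - 1
      }
    }
    stack <- section_stack(sections,
                           L_w = W * pixel_size, H_w = H * pixel_size,
                           n_x = W, n_y = H, d_s = d_s,
                           provenance = "phantom")
    truth <- structure(list(
      slices = slices,
      volume_mm3 = analytic_volume(shape),
      signal_volume_mm3 = if (is.null(blobs)) 0 else
        nrow(blobs) * 4 / 3 * pi * perturb$signal_radius_mm^3,
      blobs_mm = blobs,
      tissue_masks = tissue_masks,
      signal_masks = signal_masks,
      shape = shape, perturb = perturb,
      pixel_size = pixel_size, d_s = d_s), class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_truth> %s, %d slices, analytic volume ",
                     "%.4f mm^3, signal %.4f mm^3\n"),
              x$shape$kind, nrow(x$slices), x$volume_mm3, x$signal_volume_mm3))
  invisible(x)
}

#' Save phantom ground truth to disk
#'
#' Writes `truth.json` (per-slice transforms, analytic volumes, blob
#' positions) and per-slice tissue/signal mask PNGs alongside it.
#'
#' @param truth a `phantom_truth`.
#' @param out_dir output directory (created if missing).
#' @return The JSON path, invisibly.
#' @export
save_phantom_truth <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(truth$tissue_masks)) {
    png::writePNG(truth$tissue_masks[[k]] * 1,
                  file.path(out_dir, sprintf("tissue_mask_%04d.png", k - 1L)))
    if (any(truth$signal_masks[[k]]))
      png::writePNG(truth$signal_masks[[k]] * 1,
                    file.path(out_dir, sprintf("signal_mask_%04d.png", k - 1L)))
  }
  path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(slices = truth$slices,
                            volume_mm3 = truth$volume_mm3,
                            signal_volume_mm3 = truth$signal_volume_mm3,
                            blobs_mm = truth$blobs_mm,
                            pixel_size = truth$pixel_size, d_s = truth$d_s),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
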