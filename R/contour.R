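#' Default angular resolution for radial contours
#'
#' `max(360, ceiling(pi * max(H, W)))` angles, so adjacent rays are at most
#' about one pixel apart at the frame border.
#'
#' @param image a [section_image()].
#' @return Integer angle count.
#' @export
default_angle_count <- function(image) {
  max(360L, as.integer(ceiling(pi * max(dim(image$raster)[1:2]))))
}

new_radial_contour <- function(angles, dist, hit) {
  structure(list(angles = angles, dist = dist, hit = hit,
                 m = length(angles)), class = "radial_contour")
}

#' @export
print.radial_contour <- function(x, ...) {
  cat(sprintf("<radial_contour> %d angles, %d hits, radius %.1f..%.1f px\n",
              x$m, sum(x$hit),
              if (any(x$hit)) min(x$dist[x$hit]) else NA,
              if (any(x$hit)) max(x$dist[x$hit]) else NA))
  invisible(x)
}

#' Extract the radial contour of a centred section
#'
#' For each of `m` equally spaced angles, a ray is walked from the frame
#' border toward the frame centre; the first non-black pixel met is the
#' contour pixel and its sampled distance from the centre is recorded. Rays
#' that meet no tissue get `hit = FALSE`. The scheme assumes the section is
#' star-convex about the frame centre: only the outermost tissue along each
#' ray is seen.
#'
#' @param image a centred [section_image()] with at least one non-black
#'   pixel.
#' @param m number of angles (default [default_angle_count()]).
#' @return A `radial_contour` with fields `angles` (deg), `dist` (px) and
#'   `hit`.
#' @export
extract_contour <- function(image, m = default_angle_count(image)) {
  if (m < 4L) stopf("at least 4 contour angles are required")
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  mask <- tissue_mask(image$raster)
  if (!any(mask)) stopf("empty section: no non-black pixel")
  ctr <- frame_center(W, H)
  rmax <- sqrt(max(ctr[1], W - 1 - ctr[1])^2 + max(ctr[2], H - 1 - ctr[2])^2)
  radii <- seq(rmax, 0, by = -0.5)           # outside-in, 0.5 px steps
  angles <- (seq_len(m) - 1L) * (360 / m)
  rad <- angles * pi / 180
  xs <- round(outer(radii, cos(rad)) + ctr[1])   # nr x m pixel samples
  ys <- round(outer(radii, sin(rad)) + ctr[2])
  inside <- xs >= 0 & xs < W & ys >= 0 & ys < H
  lin <- (ys + 1L) + xs * H                      # 1-based linear index
  hitmat <- matrix(FALSE, nrow = length(radii), ncol = m)
  hitmat[inside] <- mask[lin[inside]]
  radmat <- matrix(radii, nrow = length(radii), ncol = m)
  radmat[!hitmat] <- -Inf
  dist <- apply(radmat, 2, max)                  # first hit from outside
  hit <- is.finite(dist)
  dist[!hit] <- 0
  new_radial_contour(angles, dist, hit)
}

#' Smooth contours across adjacent sections
#'
#' Reduces the slice-to-slice discontinuity of the reconstructed surface by
#' the forward pair average: for sections `n = 1..N-1`,
#' `L_n(alpha) = (l_n(alpha) + l_{n+1}(alpha)) / 2` wherever both sections
#' have a contour hit at that angle; where only one does, the original value
#' of section `n` is kept. The last contour is returned unchanged. With
#' `symmetric = TRUE` the average runs over the angles' hits in `n-1`, `n`,
#' `n+1` instead. Repeating the pass (`passes > 1`) smooths further, tending
#' toward a flat profile.
#'
#' @param contours list of `radial_contour`s in section order, all sharing
#'   one angular grid.
#' @param passes number of smoothing passes (default 1).
#' @param symmetric use the three-section window instead of the forward pair.
#' @return List of smoothed `radial_contour`s.
#' @export
smooth_contours <- function(contours, passes = 1L, symmetric = FALSE) {
  n <- length(contours)
  if (n == 0L) return(contours)
  g <- contours[[1]]$angles
  for (k in seq_len(n))
    if (!isTRUE(all.equal(contours[[k]]$angles, g)))
      stopf("contour %d uses a different angular grid", k - 1L)
  for (p in seq_len(passes)) {
    out <- contours
    for (k in seq_len(if (symmetric) n else n - 1L)) {
      acc <- contours[[k]]$dist * contours[[k]]$hit
      cnt <- as.integer(contours[[k]]$hit)
      nb <- if (symmetric) c(k - 1L, k + 1L) else k + 1L
      for (j in nb[nb >= 1L & nb <= n]) {
        acc <- acc + contours[[j]]$dist * contours[[j]]$hit
        cnt <- cnt + as.integer(contours[[j]]$hit)
      }
      use <- contours[[k]]$hit & cnt > 1L
      d <- contours[[k]]$dist
      d[use] <- (acc / cnt)[use]
      out[[k]] <- new_radial_contour(g, d, contours[[k]]$hit)
    }
    contours <- out
  }
  contours
}

#' Warp a section interior to a corrected contour
#'
#' Applies the proportional radial correction: an output pixel at polar
#' coordinates `(rho, alpha)` about the frame centre takes the input pixel at
#' radius `rho * l_old(a) / L_new(a)` along the same angle, where `a` is the
#' nearest contour grid angle. Output pixels beyond the new contour radius
#' are black. Angles without a hit in both contours are copied through
#' unchanged. Inverse mapping with nearest-neighbour sampling keeps the
#' exact-black background predicate and leaves no holes.
#'
#' @param image the centred [section_image()] `old` was extracted from.
#' @param old the contour extracted from `image`.
#' @param new the corrected contour on the same angular grid.
#' @return The warped `section_image`.
#' @export
warp_section <- function(image, old, new) {
  if (!isTRUE(all.equal(old$angles, new$angles)))
    stopf("old and new contours use different angular grids")
  if (any(old$hit & old$dist == 0))
    stopf("old contour has zero distance at a hit angle")
  H <- dim(image$raster)[1]; W <- dim(image$raster)[2]
  ctr <- frame_center(W, H)
  m <- old$m
  xs <- rep(0:(W - 1), each = H) - ctr[1]
  ys <- rep(0:(H - 1), times = W) - ctr[2]
  rho <- sqrt(xs^2 + ys^2)
  alpha <- atan2(ys, xs) * 180 / pi
  ai <- (as.integer(round(alpha / (360 / m))) %% m) + 1L
  both <- old$hit[ai] & new$hit[ai]
  lnew <- pmax(new$dist, .Machine$double.eps)
  scale <- ifelse(both, old$dist[ai] / lnew[ai], 1)
  beyond <- both & rho > new$dist[ai] + 1e-9
  rin <- rho * scale
  sx <- as.integer(round(rin * (xs / pmax(rho, .Machine$double.eps)) + ctr[1]))
  sy <- as.integer(round(rin * (ys / pmax(rho, .Machine$double.eps)) + ctr[2]))
  centrepix <- rho == 0
  sx[centrepix] <- as.integer(round(ctr[1]))
  sy[centrepix] <- as.integer(round(ctr[2]))
  ok <- both & !beyond & sx >= 0L & sx < W & sy >= 0L & sy < H
  src <- (sy + 1L) + sx * H
  out <- array(0L, dim(image$raster))
  dst <- seq_len(H * W)                  # output pixels in column-major order
  for (ch in 1:3) {
    v <- integer(H * W)
    chan <- image$raster[, , ch]
    v[dst[ok]] <- chan[src[ok]]
    v[dst[!both]] <- chan[dst[!both]]      # no contour information: copy
    out[, , ch] <- v
  }
  res <- image
  res$raster <- out
  res
}

#' Contour-correct a whole stack
#'
#' Extracts the radial contour of every retained section, smooths the
#' contours across neighbours with [smooth_contours()], and warps each
#' section to its corrected contour with [warp_section()]. Excluded sections
#' are untouched.
#'
#' @param stack a registered [section_stack()].
#' @param m angle count (default from the first retained section).
#' @param passes,symmetric passed to [smooth_contours()].
#' @return `list(stack = corrected section_stack, contours = list(old, new))`.
#' @export
smooth_stack <- function(stack, m = NULL, passes = 1L, symmetric = FALSE) {
  retained <- which(!stack_excluded(stack))
  if (length(retained) == 0L) stopf("no retained sections")
  if (is.null(m)) m <- default_angle_count(stack$sections[[retained[1]]])
  old <- lapply(retained, function(k) extract_contour(stack$sections[[k]], m))
  new <- smooth_contours(old, passes = passes, symmetric = symmetric)
  for (i in seq_along(retained)) {
    k <- retained[i]
    stack$sections[[k]] <- warp_section(stack$sections[[k]], old[[i]], new[[i]])
  }
  list(stack = add_provenance(stack, "smooth"),
       contours = list(old = old, new = new))
}

#' Total inter-section contour variation
#'
#' Sum over adjacent contour pairs and shared-hit angles of
#' `|l_{n+1}(alpha) - l_n(alpha)|`; the quantity the smoothing pass reduces.
#'
#' @param contours list of `radial_contour`s on one angular grid.
#' @return Numeric scalar.
#' @export
contour_variation <- function(contours) {
  n <- length(contours)
  if (n < 2L) return(0)
  tot <- 0
  for (k in seq_len(n - 1L)) {
    b <- contours[[k]]$hit & contours[[k + 1L]]$hit
    tot <- tot + sum(abs(contours[[k + 1L]]$dist[b] - contours[[k]]$dist[b]))
  }
  tot
}
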