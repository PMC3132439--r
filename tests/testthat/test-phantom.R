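test_that("analytic volumes match closed forms and a voxel-count oracle", {
  expect_equal(analytic_volume(shape_spec("sphere", radius = 1)), 4 * pi / 3)
  expect_equal(analytic_volume(shape_spec("ellipsoid", a = 1, b = 2, c = 3)),
               8 * pi)
  expect_equal(analytic_volume(shape_spec("cylinder", radius = 1, height = 3)),
               pi * 3)
  expect_equal(analytic_volume(shape_spec("cylinder", radius = 1, height = 2,
                                          bore_radius = 0.5)),
               pi * (1 - 0.25) * 2)

  # disjoint equal spheres: the union volume must equal two spheres
  two <- shape_spec("two-lobed-union", radius = 1, radius2 = 1,
                    separation = 3)
  expect_equal(analytic_volume(two), 8 * pi / 3)

  # independent voxel-count oracle on a fine grid, overlapping lobes too
  voxel_oracle <- function(shape, h = 0.02) {
    ext <- stack3d:::shape_extent(shape)
    gx <- seq(-ext$half_xy, ext$half_xy, by = h)
    gz <- seq(-ext$z / 2, ext$z / 2, by = h)
    n <- 0
    for (z in gz) {
      mx <- matrix(rep(gx, each = length(gx)), length(gx))
      my <- matrix(rep(gx, times = length(gx)), length(gx))
      n <- n + sum(stack3d:::shape_member(shape, mx, my, z))
    }
    n * h^3
  }
  expect_lt(abs(voxel_oracle(two) - 8 * pi / 3) / (8 * pi / 3), 0.005)
  lens <- shape_spec("two-lobed-union", radius = 1, radius2 = 0.7,
                     separation = 1.2)
  expect_lt(abs(voxel_oracle(lens) - analytic_volume(lens)) /
              analytic_volume(lens), 0.005)
})

test_that("unperturbed sphere sections are centred disks of the right size", {
  sh <- shape_spec("sphere", radius = 2)
  ph <- generate_phantom(sh, 40, 0.1, 0.02)
  expect_length(ph$stack$sections, 40)
  expect_equal(nrow(ph$truth$slices), 40)
  # middle slab samples z = 1.95 mm, cross-section radius ~99.97 px
  mid <- ph$truth$tissue_masks[[20]]
  expect_equal(sum(mid), pi * 100^2, tolerance = 0.01)
  idx <- which(mid, arr.ind = TRUE)
  ctr <- (dim(mid)[1] - 1) / 2
  expect_equal(mean(idx[, 1]) - 1, ctr, tolerance = 0.01)
  expect_equal(mean(idx[, 2]) - 1, ctr, tolerance = 0.01)
  # radius of the rendered disk
  expect_equal(max(sqrt((idx[, 1] - 1 - ctr)^2 + (idx[, 2] - 1 - ctr)^2)),
               100, tolerance = 0.02)
})

test_that("fixed seed reproduces a bit-identical stack", {
  sh <- shape_spec("sphere", radius = 1)
  pert <- perturbation_spec(translation_px = 5, rotation_deg = 20,
                            deform_amplitude = 0.05, deform_frequency = 3,
                            noise_density = 0.01, glare_count = 2,
                            signal_count = 2, signal_radius_mm = 0.2,
                            seed = 99)
  a <- generate_phantom(sh, 20, 0.1, 0.02, pert)
  b <- generate_phantom(sh, 20, 0.1, 0.02, pert)
  expect_identical(a$stack$sections, b$stack$sections)
  expect_identical(a$truth$slices, b$truth$slices)
  pert2 <- perturbation_spec(translation_px = 5, rotation_deg = 20,
                             deform_amplitude = 0.05, deform_frequency = 3,
                             noise_density = 0.01, glare_count = 2,
                             signal_count = 2, signal_radius_mm = 0.2,
                             seed = 100)
  c2 <- generate_phantom(sh, 20, 0.1, 0.02, pert2)
  expect_false(identical(a$stack$sections, c2$stack$sections))
})

test_that("summed truth mask areas approximate the analytic volume", {
  # d_s = extent / 40
  sh <- shape_spec("sphere", radius = 1)
  ph <- generate_phantom(sh, 40, 0.05, 0.02)
  v <- sum(ph$truth$slices$area) * 0.02^2 * 0.05
  expect_equal(v, 4 * pi / 3, tolerance = 0.02)
})

test_that("recorded transforms invert the perturbation up to resampling", {
  # black background so the tissue predicate holds without cleaning; the
  # mismatch sits in a ~1 px resampling band along the contour, so wide
  # cross-sections keep the differing fraction small
  sh <- shape_spec("sphere", radius = 2, background_tone = c(0, 0, 0))
  pert <- perturbation_spec(translation_px = 10, rotation_deg = 30, seed = 4)
  ph <- generate_phantom(sh, 20, 0.2, 0.015, pert, frame_px = 301)
  ref <- generate_phantom(sh, 20, 0.2, 0.015, frame_px = 301)
  mismatch <- tissue <- 0
  for (k in 8:13) {
    tr <- ph$truth$slices[k, ]
    img <- ph$stack$sections[[k]]
    # inverse of (rotate, then translate): untranslate, then unrotate
    r <- img$raster
    H <- dim(r)[1]; W <- dim(r)[2]
    out <- array(0L, dim(r))
    ys <- max(1, 1 + tr$dy):min(H, H + tr$dy)
    xs <- max(1, 1 + tr$dx):min(W, W + tr$dx)
    out[ys - tr$dy, xs - tr$dx, ] <- r[ys, xs, , drop = FALSE]
    und <- rotate_section(section_image(out), -tr$theta)
    got <- stack3d:::tissue_mask(und$raster)
    want <- ref$truth$tissue_masks[[k]]
    mismatch <- mismatch + sum(got != want)
    tissue <- tissue + sum(want)
  }
  expect_lt(mismatch / tissue, 0.01)
})

test_that("a too-small frame fails naming the first offending slice", {
  sh <- shape_spec("sphere", radius = 1)
  # cross-sections reach the 40 px half-frame once sqrt(1 - dz^2) >= 0.8 mm,
  # first at slab 4 (z = 0.45 mm)
  expect_error(generate_phantom(sh, 20, 0.1, 0.02, frame_px = 81),
               "slice 4")
})

test_that("slices beyond the shape are generated but flagged excluded", {
  sh <- shape_spec("cylinder", radius = 0.5, height = 1)
  ph <- generate_phantom(sh, 14, 0.1, 0.02)   # 1.4 mm of slabs for 1 mm shape
  excl <- vapply(ph$stack$sections, `[[`, logical(1), "excluded")
  expect_identical(excl, c(TRUE, TRUE, rep(FALSE, 10), TRUE, TRUE))
  expect_equal(nrow(ph$truth$slices), 14)
})

test_that("phantom truth round-trips to disk", {
  sh <- shape_spec("sphere", radius = 0.5)
  pert <- perturbation_spec(signal_count = 1, signal_radius_mm = 0.15,
                            seed = 2)
  ph <- generate_phantom(sh, 10, 0.1, 0.02, pert)
  dir <- withr::local_tempdir()
  path <- save_phantom_truth(ph$truth, dir)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$volume_mm3, ph$truth$volume_mm3)
  expect_equal(nrow(got$slices), 10)
  expect_true(file.exists(file.path(dir, "tissue_mask_0004.png")))
})
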