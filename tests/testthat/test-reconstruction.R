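test_that("voxel dimensions follow the calibration proportions", {
  stack <- raster_stack(list(disk_raster(21, r = 5)), pixel = 0.01,
                        d_s = 0.06)
  vd <- compute_voxel_dims(stack)
  expect_equal(vd$x, 0.01)
  expect_equal(vd$y, 0.01)
  expect_equal(vd$z, 0.06)

  # explicit calibration: 5 mm over 500 px
  s <- section_stack(list(section_image(disk_raster(21, r = 5))),
                     L_w = 5, H_w = 5, n_x = 500, n_y = 500, d_s = 0.06)
  # frame is 21 px but calibration is carried independently
  vd2 <- compute_voxel_dims(s)
  expect_equal(vd2$x, 0.01)
  expect_equal(vd2$z, 0.06)

  s$calibration$H_w <- 4
  expect_error(compute_voxel_dims(s), "non-square")
})

test_that("assembly stacks slabs in order and fills exclusions", {
  rs <- list(disk_raster(31, r = 10), disk_raster(31, r = 8),
             disk_raster(31, r = 6))
  stack <- raster_stack(rs)
  vol <- assemble_volume(stack)
  expect_equal(dim(vol$grid), c(31, 31, 3, 3))
  for (k in 1:3) expect_identical(vol$grid[, , , k], rs[[k]])
  expect_identical(vol$source_index, 0:2)

  # excluded middle slab copies the earlier neighbour (tie -> earlier)
  stack2 <- raster_stack(rs, excluded = c(FALSE, TRUE, FALSE))
  vol2 <- assemble_volume(stack2)
  expect_identical(vol2$grid[, , , 2], rs[[1]])
  expect_identical(vol2$source_index, c(0L, 0L, 2L))

  expect_error(assemble_volume(raster_stack(rs, excluded = rep(TRUE, 3))),
               "excluded")
})

test_that("tissue volume is voxel count times voxel volume", {
  grid <- raster_stack(lapply(1:10, function(i) flat_raster(10, 10,
                                                            c(128, 128, 128))),
                       pixel = 0.1, d_s = 0.1)
  vol <- assemble_volume(grid)
  expect_equal(measure_volume(vol), 1.0)     # 1000 voxels x 0.001 mm^3

  empty <- raster_stack(lapply(1:3, function(i) {
    r <- flat_raster(10, 10, c(0, 0, 0)); r[1, 1, 1] <- 1L; r
  }), pixel = 0.1, d_s = 0.1)
  vole <- assemble_volume(empty)
  expect_equal(measure_volume(vole), 3 * 0.001)

  # additivity over a partition into boxes
  sh <- shape_spec("sphere", radius = 0.5, background_tone = c(0, 0, 0))
  ph <- generate_phantom(sh, 10, 0.1, 0.02)
  v <- assemble_volume(ph$stack)
  whole <- measure_volume(v)
  d <- dim(v$grid)
  half1 <- measure_volume(v, list(x = c(0, 24), y = c(0, d[1] - 1),
                                  z = c(0, d[4] - 1)))
  half2 <- measure_volume(v, list(x = c(25, d[2] - 1), y = c(0, d[1] - 1),
                                  z = c(0, d[4] - 1)))
  expect_equal(half1 + half2, whole)
  expect_error(measure_volume(v, list(x = c(0, 999), y = c(0, 1),
                                      z = c(0, 1))), "outside")
})

test_that("phantom sphere volume converges as spacing shrinks", {
  sh <- shape_spec("sphere", radius = 1, background_tone = c(0, 0, 0))
  errs <- vapply(c(10, 20, 40), function(n) {
    ph <- generate_phantom(sh, n, 2 / n, 0.01)
    v <- measure_volume(assemble_volume(ph$stack))
    abs(v - 4 * pi / 3) / (4 * pi / 3)
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("enclosed cavities are measured per slab", {
  # solid stack has no cavity
  solid <- assemble_volume(raster_stack(lapply(1:3, function(i)
    disk_raster(41, r = 15))))
  expect_equal(measure_cavity_volume(solid), 0)

  # stacked annuli: cavity equals the bore cylinder
  annulus <- disk_raster(121, r = 50)
  xs <- matrix(rep(0:120, each = 121), 121)
  ys <- matrix(rep(0:120, times = 121), 121)
  hole <- (xs - 60)^2 + (ys - 60)^2 <= 20^2
  for (ch in 1:3) annulus[, , ch][hole] <- 0L
  stack <- raster_stack(lapply(1:10, function(i) annulus),
                        pixel = 0.02, d_s = 0.05)
  vol <- assemble_volume(stack)
  got <- measure_cavity_volume(vol)
  want <- pi * 20^2 * 10 * 0.02^2 * 0.05
  expect_equal(got, want, tolerance = 0.02)

  # phantom cylinder with a coaxial bore
  sh <- shape_spec("cylinder", radius = 1, height = 1, bore_radius = 0.4,
                   background_tone = c(0, 0, 0))
  ph <- generate_phantom(sh, 10, 0.1, 0.01)
  volb <- assemble_volume(ph$stack)
  bore <- pi * 0.4^2 * 1
  expect_equal(measure_cavity_volume(volb), bore, tolerance = 0.02)
})

test_that("MetaImage export round-trips voxels and spacing", {
  sh <- shape_spec("sphere", radius = 0.3, background_tone = c(0, 0, 0))
  ph <- generate_phantom(sh, 10, 0.06, 0.02)
  vol <- assemble_volume(ph$stack)
  dir <- withr::local_tempdir()
  hdr <- export_volume(vol, file.path(dir, "vol"), "mhd")
  expect_true(file.exists(hdr))
  expect_true(file.exists(file.path(dir, "vol.raw")))
  back <- import_mhd(hdr)
  expect_identical(back$grid, vol$grid)
  expect_equal(unclass(back$dims), unclass(vol$dims), tolerance = 1e-9)

  # header metadata: spacing to 1e-6, from the Lw=5/nx=500/ds=0.06 proportions
  s <- section_stack(lapply(0:1, function(k)
    section_image(disk_raster(21, r = 5), index = k)),
    L_w = 21 * 0.01, H_w = 21 * 0.01, n_x = 21, n_y = 21, d_s = 0.06)
  vol2 <- assemble_volume(s)
  hdr2 <- export_volume(vol2, file.path(dir, "cal"), "mhd")
  line <- grep("ElementSpacing", readLines(hdr2), value = TRUE)
  got <- as.numeric(strsplit(sub(".*= ", "", line), " ")[[1]])
  expect_equal(got, c(0.01, 0.01, 0.06), tolerance = 1e-6)

  # anisotropy is carried exactly (z = 4x in-plane: 15 um px, 60 um slabs)
  s$d_s <- 4 * 0.01
  vol3 <- assemble_volume(s)
  hdr3 <- export_volume(vol3, file.path(dir, "aniso"), "mhd")
  line3 <- grep("ElementSpacing", readLines(hdr3), value = TRUE)
  got3 <- as.numeric(strsplit(sub(".*= ", "", line3), " ")[[1]])
  expect_equal(got3[3], 4 * got3[1], tolerance = 1e-9)

  expect_error(export_volume(vol, file.path(dir, "x"), "jpeg"))
})

test_that("NIfTI export carries dimensions and physical spacing", {
  sh <- shape_spec("sphere", radius = 0.3, background_tone = c(0, 0, 0))
  ph <- generate_phantom(sh, 10, 0.06, 0.02)
  vol <- assemble_volume(ph$stack)
  dir <- withr::local_tempdir()
  out <- export_volume(vol, file.path(dir, "vol"), "nifti")
  img <- RNifti::readNifti(out)
  d <- dim(vol$grid)
  expect_equal(dim(img), c(d[2], d[1], d[4]))
  expect_equal(RNifti::pixdim(img), c(0.02, 0.02, 0.06), tolerance = 1e-6)
  # luminance of pure grey tissue is the grey level itself
  expect_equal(sum(img > 0), sum(stack3d:::volume_tissue_array(vol)))
})
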