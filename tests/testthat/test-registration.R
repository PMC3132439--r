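test_that("centroid equals the brute-force coordinate average", {
  r <- array(0L, c(40, 40, 3))
  r[21, 11, ] <- 128L                      # pixel (x=10, y=20)
  expect_equal(unname(compute_centroid(section_image(r))), c(10, 20))

  # filled rectangle with corners (10,10)-(20,30)
  r <- array(0L, c(64, 64, 3))
  r[11:31, 11:21, ] <- 100L
  expect_equal(unname(compute_centroid(section_image(r))), c(15, 20))

  # 500 random pixels vs an explicit loop
  set.seed(7)
  r <- array(0L, c(50, 60, 3))
  pick <- sample(50 * 60, 500)
  r[, , 1][pick] <- 200L
  sx <- sy <- 0; n <- 0
  for (x in 0:59) for (y in 0:49) if (r[y + 1, x + 1, 1] != 0) {
    sx <- sx + x; sy <- sy + y; n <- n + 1
  }
  expect_equal(unname(compute_centroid(section_image(r))),
               c(sx / n, sy / n), tolerance = 1e-9)

  expect_error(compute_centroid(section_image(array(0L, c(5, 5, 3)))),
               "empty")
})

test_that("centring shifts the barycentre onto the frame centre", {
  # already centred disk: zero shift, image untouched
  img <- section_image(disk_raster(41, r = 10))
  cen <- center_section(img)
  expect_identical(cen$offset$shift, c(0L, 0L))
  expect_identical(cen$image$raster, img$raster)

  # disk at (centre - 7, centre + 3) comes back with shift (7, -3)
  img2 <- section_image(disk_raster(41, r = 10, cx = 20 - 7, cy = 20 + 3))
  cen2 <- center_section(img2)
  expect_identical(cen2$offset$shift, c(7L, -3L))
  expect_identical(cen2$image$raster, img$raster)
  expect_equal(sum(stack3d:::tissue_mask(cen2$image$raster)),
               sum(stack3d:::tissue_mask(img2$raster)))
  # recomputed centroid sits within 0.5 px of the frame centre
  expect_true(all(abs(compute_centroid(cen2$image) - 20) <= 0.5))

  # idempotence
  cen3 <- center_section(cen2$image)
  expect_identical(cen3$offset$shift, c(0L, 0L))

  # tissue spanning the full frame height cannot be shifted vertically
  r4 <- array(0L, c(41, 41, 3))
  r4[, 19:25, ] <- 120L                    # full-height bar
  r4[1:5, 11:31, ] <- 120L                 # off-centre mass forces a dy shift
  expect_error(center_section(section_image(r4)), "pad")
})

test_that("rotation search recovers known angles and reports its curve", {
  base <- disk_raster(61, r = 20)
  base[16:31, 29:33, ] <- 0L               # notch breaks rotational symmetry
  img <- section_image(base)

  # identity alignment
  res <- align_rotation(img, img)
  expect_equal(res$result$angle, 0)
  expect_equal(res$result$d, 0)
  expect_equal(nrow(res$result$curve), 360)

  # rotate by our own resampler, search must undo it
  for (theta in c(30, 117, 290)) {
    rot <- rotate_section(img, theta)
    got <- align_rotation(rot, img)$result$angle
    expect_lte(min(abs(stack3d:::wrap_angle(got + theta))), 1)
  }

  # optimality of the returned angle against its own curve
  rot <- rotate_section(img, 45)
  res2 <- align_rotation(rot, img)
  expect_equal(res2$result$d, min(res2$result$curve$d))

  # rotationally symmetric disk: near-flat curve, tie-break picks 0
  disk <- section_image(disk_raster(61, r = 20))
  res3 <- align_rotation(disk, disk)
  expect_equal(res3$result$angle, 0)

  expect_error(align_rotation(img, section_image(disk_raster(31, r = 5))),
               "dimensions")
  expect_error(align_rotation(img, img, angular_step = 7), "divisor")
})

test_that("90-degree search agrees with an independent four-way comparison", {
  set.seed(11)
  for (rep in 1:3) {
    a <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
    a[sample(32 * 32, 300)] <- 0L
    b <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
    lum <- function(r) round(0.299 * r[, , 1] + 0.587 * r[, , 2] +
                             0.114 * r[, , 3])
    la <- lum(a); lb <- lum(b)
    # explicit nearest-neighbour source lookup, angle by angle
    oracle <- vapply(c(0, 90, 180, 270), function(theta) {
      th <- theta * pi / 180
      tot <- 0
      for (x in 0:31) for (y in 0:31) {
        sx <- round(cos(th) * (x - 15.5) + sin(th) * (y - 15.5) + 15.5)
        sy <- round(-sin(th) * (x - 15.5) + cos(th) * (y - 15.5) + 15.5)
        v <- if (sx >= 0 && sx < 32 && sy >= 0 && sy < 32)
          la[sy + 1, sx + 1] else 0
        tot <- tot + abs(v - lb[y + 1, x + 1])
      }
      tot
    }, numeric(1))
    res <- align_rotation(section_image(a), section_image(b),
                          angular_step = 90)
    expect_equal(res$result$curve$d, oracle)
    expect_equal(res$result$angle, c(0, 90, 180, 270)[which.min(oracle)])
  }
})

test_that("chain registration recovers phantom transforms", {
  sh <- shape_spec("cylinder", radius = 1.2, height = 2.4,
                   bore_radius = c(0.38, 0.32), bore_offset = c(0.55, -0.7756))
  pert <- perturbation_spec(translation_px = 10, rotation_deg = 30, seed = 8)
  ph <- generate_phantom(sh, 12, 0.2, 0.02, pert)
  reg <- register_stack(clean_stack(ph$stack, std_ranges()))
  ev <- evaluate_registration(reg$diagnostics, ph$truth, ph$stack)
  expect_true(all(ev$trans_err_px <= 1))
  expect_true(all(ev$rot_err_deg <= 1))
  # optimality across every stored curve
  for (cur in reg$curves) expect_true(min(cur$d) %in% cur$d[cur$d == min(cur$d)])
  for (i in seq_len(nrow(reg$diagnostics))) {
    if (is.na(reg$diagnostics$d[i])) next
    cur <- reg$curves[[as.character(reg$diagnostics$index[i])]]
    expect_equal(reg$diagnostics$d[i], min(cur$d))
  }
})

test_that("single sections anchor and excluded sections are skipped", {
  one <- raster_stack(list(disk_raster(41, r = 8, cx = 15, cy = 25)))
  reg <- register_stack(one)
  expect_equal(nrow(reg$diagnostics), 1)
  expect_equal(reg$diagnostics$theta, 0)
  expect_true(all(abs(compute_centroid(reg$stack$sections[[1]]) - 20) <= 0.5))

  base <- disk_raster(41, r = 9)
  base[12:20, 19:23, ] <- 0L
  rs <- list(base, disk_raster(41, r = 9), base)
  stack <- raster_stack(rs, excluded = c(FALSE, TRUE, FALSE))
  reg2 <- register_stack(stack)
  expect_identical(reg2$diagnostics$index, c(0L, 2L))
  # excluded section untouched
  expect_identical(reg2$stack$sections[[2]]$raster, rs[[2]])
  # section 2 aligned to section 0 (its nearest retained predecessor)
  expect_equal(reg2$diagnostics$theta[2], 0)

  allex <- raster_stack(rs, excluded = rep(TRUE, 3))
  expect_error(register_stack(allex), "no retained")
})
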