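make_rot_band <- function(width, length, angle, canvas = NULL, seed = 1) {
  generate_band(band_spec(true_width = width, length = length, angle = angle,
                          canvas = canvas, pixel_size = 1, seed = seed))$truth
}

test_that("cropping copies pixels, keeps calibration and respects bounds", {
  set.seed(7)
  m <- random_mask(20, 30, pixel_size = 4)
  full <- crop_mask(m, rect_roi(0, 20, 0, 30))
  expect_identical(full$pixels, m$pixels)
  expect_equal(full$pixel_size, 4)

  fg <- which(m$pixels == 1, arr.ind = TRUE)[1, ]
  one <- crop_mask(m, rect_roi(fg[1] - 1, fg[1], fg[2] - 1, fg[2]))
  expect_equal(dim(one$pixels), c(1L, 1L))
  expect_equal(one$pixels[1, 1], 1)

  expect_error(crop_mask(m, rect_roi(0, 21, 0, 30)), "bounds")
  expect_error(crop_mask(m, rect_roi(0, 20, 5, 31)), "bounds")
})

test_that("a disjoint ROI tiling partitions the foreground count", {
  set.seed(8)
  for (i in 1:5) {
    m <- random_mask(24, 18)
    cut_r <- sample(1:23, 1)
    a <- crop_mask(m, rect_roi(0, cut_r, 0, 18))
    b <- crop_mask(m, rect_roi(cut_r, 24, 0, 18))
    # brute-force count oracle
    total <- 0L
    for (r in 1:24) for (cc in 1:18) total <- total + m$pixels[r, cc]
    expect_equal(sum(a$pixels) + sum(b$pixels), total)
  }
})

test_that("axis estimation recovers band orientation", {
  vert <- make_rot_band(5, 200, 0)
  expect_lt(abs(axis_angle(estimate_axis(vert))), 0.5)

  rot30 <- make_rot_band(5, 200, 30)
  expect_lt(abs(axis_angle(estimate_axis(rot30)) - 30), 1)
})

test_that("a single-row line yields its leftmost and rightmost pixels", {
  m <- matrix(0, 9, 20)
  m[5, 4:15] <- 1
  ax <- estimate_axis(binary_mask(m, 1))
  expect_equal(ax$p1, c(4, 3))   # 0-based (row, col)
  expect_equal(ax$p2, c(4, 14))
  expect_equal(axis_angle(ax), 90)
})

test_that("axis estimation fails cleanly on degenerate foregrounds", {
  expect_error(estimate_axis(binary_mask(matrix(0, 5, 5), 1)), "2 foreground")
  sq <- matrix(0, 20, 20); sq[5:14, 5:14] <- 1     # isotropic
  expect_error(estimate_axis(binary_mask(sq, 1)), "isotropic|ambiguous")
})

test_that("axis estimation is translation invariant and 90-degree equivariant", {
  base <- make_rot_band(6, 80, 20)
  a0 <- axis_angle(estimate_axis(base))

  shifted <- rbind(matrix(0, 7, ncol(base$pixels) + 5),
                   cbind(matrix(0, nrow(base$pixels), 5), base$pixels))
  expect_equal(axis_angle(estimate_axis(binary_mask(shifted, 1))), a0,
               tolerance = 1e-10)

  # rotate the mask grid by 90 degrees counter-clockwise
  rot90 <- t(base$pixels)[ncol(base$pixels):1, ]
  a90 <- axis_angle(estimate_axis(binary_mask(rot90, 1)))
  d <- (a0 - a90) %% 180
  expect_lt(min(d, 180 - d, abs(d - 90)), 1e-6)
})

test_that("alignment leaves a vertical band unchanged and keeps calibration", {
  vert <- make_rot_band(5, 120, 0)
  al <- align_vertical(vert)
  expect_identical(al$pixels, vert$pixels)
  expect_equal(al$pixel_size, vert$pixel_size)
})

test_that("aligning a horizontal band recovers its height", {
  m <- matrix(0, 40, 200)
  m[15:22, 20:180] <- 1                     # 8 rows tall, horizontal
  mask <- binary_mask(m, 2.5)
  # brute-force per-column count on the unrotated mask
  col_heights <- colSums(m[, 20:180])
  expect_true(all(col_heights == 8))
  al <- align_vertical(mask)
  res <- measure_slice(al)
  expect_lt(abs(res$mean - 8 * 2.5), 1 * 2.5)
})

test_that("width survives alignment of an oblique band within a pixel", {
  b <- make_rot_band(12, 100, 17)
  al <- align_vertical(b)
  res <- measure_slice(al)
  expect_lt(abs(res$mean - 12), 1)
})

test_that("rotation forward and back preserves most of the foreground", {
  # the nearest-neighbour resampling bound scales with the band's
  # perimeter/area ratio, so it is checked on a representatively thick band
  for (ang in c(10, 25, 40)) {
    b <- make_rot_band(30, 150, ang)
    al <- align_vertical(b)                  # -ang degrees
    back_axis <- axis_endpoints(c(0, 0),
                                c(cos(-ang * pi / 180), sin(-ang * pi / 180)))
    back <- align_vertical(al, back_axis)    # +ang degrees

    # compare shapes up to integer translation (canvas padding is
    # arbitrary): register at the best offset near the centroid difference
    fp1 <- which(b$pixels == 1, arr.ind = TRUE)
    fp2 <- which(back$pixels == 1, arr.ind = TRUE)
    d0 <- round(colMeans(fp2) - colMeans(fp1))
    k1 <- paste(fp1[, 1], fp1[, 2])
    best <- Inf
    for (dr in (d0[1] - 1):(d0[1] + 1)) {
      for (dc in (d0[2] - 1):(d0[2] + 1)) {
        k2 <- paste(fp2[, 1] - dr, fp2[, 2] - dc)
        mism <- length(union(k1, k2)) - length(intersect(k1, k2))
        best <- min(best, mism)
      }
    }
    expect_lt(best / nrow(fp1), 0.03)
  }
})

test_that("the largest connected object survives speck removal", {
  m <- matrix(0, 30, 30)
  m[5:25, 10:14] <- 1                        # band, 105 px
  m[2, 2] <- 1; m[28, 28] <- 1; m[3, 27] <- 1
  sel <- select_band(binary_mask(m, 1))
  expect_equal(sum(sel$pixels), 105)
  expect_equal(sel$pixels[5:25, 10:14], matrix(1, 21, 5))
  expect_error(select_band(binary_mask(matrix(0, 4, 4), 1)), "no foreground")
})
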