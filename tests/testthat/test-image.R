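disk_image <- function(np = 120, r_frac = 0.8, value = 100) {
  img <- matrix(0, np, np)
  c0 <- (np + 1) / 2
  for (j in seq_len(np)) {
    d2 <- (seq_len(np) - c0)^2 + (j - c0)^2
    img[d2 <= (r_frac * np / 2)^2, j] <- value
  }
  img
}

ring_image <- function(np = 120, r_frac = 0.85, mask_frac = 0.95,
                       width = 2, value = 100, floor_val = 1) {
  img <- matrix(0, np, np)
  c0 <- (np + 1) / 2
  for (j in seq_len(np)) {
    d <- sqrt((seq_len(np) - c0)^2 + (j - c0)^2)
    inside <- d <= mask_frac * np / 2
    img[inside, j] <- floor_val
    sel <- abs(d - r_frac * mask_frac * np / 2) <= width & inside
    img[sel, j] <- value
  }
  img
}

test_that("mask and centroid find the cell and ignore detached specks", {
  im <- intensity_image(disk_image(), pixel_nm = 100)
  mc <- mask_and_centroid(im)
  expect_equal(mc$centroid, c(60.5, 60.5), tolerance = 1 / 60)
  # detached bright speck is dropped by the largest-component rule
  img2 <- disk_image()
  img2[3:4, 3:4] <- 500
  mc2 <- mask_and_centroid(intensity_image(img2, 100))
  expect_false(mc2$mask[3, 3])
  expect_error(mask_and_centroid(intensity_image(matrix(0, 10, 10), 100)),
               "empty")
})

test_that("background subtraction clips negatives", {
  im <- intensity_image(matrix(c(5, 1), 2, 2), 100, background = 2)
  expect_true(all(im$img >= 0))
  expect_equal(im$img[1, 1], 3)
})

test_that("radial profiles are 50 rays normalized to the mask edge", {
  im <- intensity_image(ring_image(), pixel_nm = 100)
  mc <- mask_and_centroid(im, threshold = 0.5)
  pr <- radial_profiles(im, mc$mask, mc$centroid)
  expect_equal(length(unique(pr$ray)), 50L)
  expect_true(all(pr$r >= 0 & pr$r <= 1))
  # rotational symmetry: per-ray intensity peaks at the same radius
  peaks <- tapply(seq_len(nrow(pr)), pr$ray,
                  function(i) pr$r[i][which.max(pr$intensity[i])])
  expect_lt(stats::sd(peaks), 0.03)
  expect_error(radial_profiles(im, mc$mask, c(1, 1)), "outside mask")
})

test_that("intensity radial median matches analytic fixtures", {
  # threshold at half maximum so the mask edge sits on the true disk edge
  im <- intensity_image(disk_image(r_frac = 0.9), pixel_nm = 100)
  q <- quantify_image(im, threshold = 50)
  expect_equal(q$r_median, 1 / sqrt(2), tolerance = 0.02)
  imr <- intensity_image(ring_image(r_frac = 0.85, floor_val = 0.2),
                         pixel_nm = 100)
  qr <- quantify_image(imr, threshold = 0.1)
  expect_equal(qr$r_median, 0.85, tolerance = 0.02)
  # intensity concentrated at the centroid of a dim cell mask
  img0 <- disk_image(np = 100, r_frac = 0.8, value = 1)
  img0[48:52, 48:52] <- 1000
  q0 <- quantify_image(intensity_image(img0, 100), threshold = 0.5)
  expect_lt(q0$r_median, 0.2)
  expect_error(intensity_r_median(data.frame(ray = 1, r = 0.5,
                                             intensity = 0)),
               "zero total")
})

test_that("image quantification is invariant to intensity scaling and
          rotation", {
  im <- intensity_image(ring_image(floor_val = 0.2), pixel_nm = 100)
  q1 <- quantify_image(im, threshold = 0.1)
  q2 <- quantify_image(intensity_image(im$img * 7, 100), threshold = 0.7)
  expect_equal(q1$r_median, q2$r_median, tolerance = 0.01)
  # 90-degree rotation
  rot <- t(im$img)[ncol(im$img):1, ]
  q3 <- quantify_image(intensity_image(rot, 100), threshold = 0.1)
  expect_equal(q1$r_median, q3$r_median, tolerance = 0.01)
})

test_that("plateau slope recovers a constructed ramp profile", {
  # synthetic profiles: I(r) = r up to 0.6, then flat plateau at 0.6
  mkprof <- function(scale = 1) {
    r <- rep(seq(0.01, 1, by = 0.01), times = 50)
    data.frame(ray = rep(1:50, each = 100), r = r,
               intensity = scale * pmin(r, 0.6))
  }
  ps <- plateau_slope(list(mkprof()), times = 0)
  # slopes are in bleach-normalized units: I/mean(I) per unit r; the
  # constructed ramp has slope 1 before normalization
  mean_i <- mean(mkprof()$intensity)
  expect_equal(ps$slope[1] * mean_i, 1, tolerance = 0.05)
  # identical frames give a constant slope series
  ps3 <- plateau_slope(list(mkprof(), mkprof(), mkprof()), times = 0:2)
  expect_equal(ps3$slope, rep(ps3$slope[1], 3))
  # global exponential bleaching is removed by mean normalization
  ps4 <- plateau_slope(list(mkprof(1), mkprof(0.8), mkprof(0.64)),
                       times = 0:2)
  expect_lt(diff(range(ps4$slope)) / abs(mean(ps4$slope)), 0.02)
})
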