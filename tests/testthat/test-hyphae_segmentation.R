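test_that("Gaussian smoothing preserves constants, mass and the mean", {
  expect_equal(smooth_brightfield(matrix(100, 20, 20), 3),
               matrix(100, 20, 20))

  # unit impulse: center equals the discrete 2-D kernel peak, total intensity
  # conserved within per-pixel rounding
  img <- matrix(0, 41, 41); img[21, 21] <- 255
  sm <- smooth_brightfield(img, 3)
  w <- hyphacover:::gaussian_kernel(3)
  expect_equal(sm[21, 21], round(255 * max(w)^2))
  expect_lt(abs(sum(sm) - 255), length(w)^2 * 0.5)

  set.seed(21)
  noisy <- matrix(pmin(255, pmax(0, round(rnorm(60 * 60, 128, 15)))), 60, 60)
  expect_lt(abs(mean(smooth_brightfield(noisy, 3)) - mean(noisy)), 0.5)
})

test_that("Sobel magnitude is zero on constants and localized on a step", {
  expect_equal(sobel_contour(matrix(7, 15, 15)), matrix(0, 15, 15))

  # vertical step 0 | 200: response only in the two columns adjacent to the
  # step; interior rows of those columns share one value
  img <- cbind(matrix(0, 20, 10), matrix(200, 20, 10))
  g <- sobel_contour(img)
  expect_true(all(g[, c(1:9, 12:20)] == 0))
  expect_true(all(g[, 10:11] > 0))
  expect_length(unique(g[2:19, 10]), 1)
  expect_length(unique(g[2:19, 11]), 1)
})

test_that("Sobel magnitude commutes with 90-degree rotation", {
  set.seed(5)
  img <- random_image8(24, 17)
  expect_equal(sobel_contour(rot90(img)), rot90(sobel_contour(img)))
})

test_that("line structuring elements are symmetric digital lines through the origin", {
  for (a in c(0, 45, 90, 135)) {
    fp <- line_footprint(a, 9)
    expect_equal(nrow(fp), 9)
    expect_true(any(fp[, 1] == 0 & fp[, 2] == 0))
    # symmetric about the origin
    expect_setequal(paste(fp[, 1], fp[, 2]), paste(-fp[, 1], -fp[, 2]))
  }
  expect_error(line_footprint(30, 9), "0, 45, 90, 135")
  expect_error(line_footprint(0, 8), "odd")
})

test_that("directional closing is extensive, idempotent and matches the brute-force oracle", {
  set.seed(7)
  for (rep in 1:5) {
    img <- random_image8(20, 20)
    closed <- directional_close(img, length = 5)
    expect_true(all(closed >= img))
    for (a in c(0, 45, 90, 135)) {
      fp <- line_footprint(a, 5)
      one <- directional_close(img, angles = a, length = 5)
      expect_equal(one, oracle_close(img, fp))
      expect_equal(directional_close(one, angles = a, length = 5), one)
    }
  }
  expect_equal(directional_close(matrix(42, 12, 12), length = 5),
               matrix(42, 12, 12))
})

test_that("closing bridges a one-pixel gap in a ridge", {
  img <- matrix(0, 11, 15)
  img[6, c(3:7, 9:13)] <- 200  # horizontal ridge, gap at column 8
  closed <- directional_close(img, angles = 0, length = 5)
  expect_equal(closed[6, 8], 200)
  expect_equal(closed, oracle_close(img, line_footprint(0, 5)))
})

test_that("directional opening is anti-extensive, idempotent and keeps full-length runs", {
  set.seed(9)
  for (rep in 1:5) {
    mask <- matrix(runif(20 * 20) < 0.4, 20, 20)
    opened <- directional_open(mask, length = 5)
    expect_true(all(opened <= mask))
    for (a in c(0, 45, 90, 135)) {
      fp <- line_footprint(a, 5)
      one <- directional_open(mask, angles = a, length = 5)
      expect_equal(one * 1, oracle_open(mask * 1, fp))
      expect_equal(directional_open(one, angles = a, length = 5), one)
    }
  }
  # single isolated pixel is removed
  mask <- matrix(FALSE, 11, 11); mask[6, 6] <- TRUE
  expect_false(any(directional_open(mask, length = 3)))
  # a horizontal run of exactly `length` pixels survives in full
  mask <- matrix(FALSE, 9, 15); mask[5, 6:10] <- TRUE
  expect_equal(directional_open(mask, length = 5), mask)
})

test_that("IsoData threshold matches its fixed-point definition", {
  # equal masses at 50 and 150: fixed point of (50 + 150) / 2
  img <- matrix(c(50, 150), 16, 16)
  th <- auto_threshold_default(img)
  expect_equal(th$threshold, 100)
  expect_equal(unclass(th$mask), img > 100, ignore_attr = TRUE)

  expect_error(auto_threshold_default(matrix(7, 8, 8)), "degenerate")

  set.seed(13)
  for (rep in 1:200) {
    v <- sample(0:255, 400, replace = TRUE,
                prob = runif(256)^sample(1:4, 1))
    img <- matrix(v, 20, 20)
    if (length(unique(v)) < 2) next
    t_hat <- auto_threshold_default(img)$threshold
    fixed <- oracle_isodata_fixed_points(v)
    expect_true(t_hat %in% fixed)
    if (length(fixed) == 1) expect_equal(t_hat, fixed)
  }
})

test_that("hyphae segmentation recovers a straight synthetic filament", {
  p <- synthetic_params(seed = 3, n_filaments = 1, max_turn = 0,
                        n_bacteria_on = 0, n_bacteria_off = 0,
                        height = 256, width = 256)
  sc <- render_scene(p)
  mask <- segment_hyphae(sc$fov$brightfield)
  truth <- sc$truth_hyphae_mask
  # the contour-band mask covers the filament almost completely ...
  expect_gt(sum(mask & truth) / sum(truth), 0.9)
  # ... and stays confined to a narrow neighbourhood of it: the smoothing
  # radius widens the detected band by a few pixels on each side
  near <- as.matrix(EBImage::dilate(truth * 1,
                                    hyphacover:::disk_kernel(8))) > 0.5
  expect_gt(sum(mask & near) / sum(mask), 0.95)
})

test_that("hyphae segmentation is exactly 90-degree equivariant", {
  p <- synthetic_params(seed = 4, height = 128, width = 128, n_filaments = 2,
                        n_bacteria_on = 0, n_bacteria_off = 0)
  bf <- render_scene(p)$fov$brightfield
  m1 <- segment_hyphae(rot90(bf))
  m2 <- rot90(unclass(segment_hyphae(bf)))
  expect_equal(unclass(m1), m2, ignore_attr = TRUE)
})

test_that("blank bright-field raises a degenerate-input error", {
  expect_error(segment_hyphae(matrix(128, 64, 64)), "degenerate")
})

test_that("opened mask area is non-increasing in line length", {
  # a longer line always contains a shorter one, so surviving pixels of the
  # longer opening survive the shorter opening too
  set.seed(22)
  for (rep in 1:5) {
    mask <- matrix(runif(40 * 40) < 0.45, 40, 40)
    areas <- sapply(c(3, 5, 9, 13), function(len) {
      sum(directional_open(mask, length = len))
    })
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("hole filling fills the interior of a closed contour", {
  mask <- matrix(FALSE, 21, 21)
  mask[6:16, 6] <- TRUE; mask[6:16, 16] <- TRUE
  mask[6, 6:16] <- TRUE; mask[16, 6:16] <- TRUE
  filled <- fill_holes(mask)
  expect_true(all(filled[7:15, 7:15]))
  expect_false(any(filled[1:4, ]))
})
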