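test_that("rolling-ball subtraction removes flat backgrounds and constant offsets", {
  flat <- matrix(37, 64, 64)
  expect_equal(rolling_ball_subtract(flat, 20), matrix(0, 64, 64))
  expect_equal(rolling_ball_subtract(flat, 20, presmooth = FALSE),
               matrix(0, 64, 64))

  set.seed(31)
  img <- matrix(sample(0:200, 64 * 64, replace = TRUE), 64, 64)
  plus_k <- pmin(img + 30, 255)
  expect_equal(rolling_ball_subtract(plus_k, 10),
               rolling_ball_subtract(img, 10))
  expect_equal(rolling_ball_subtract(plus_k, 10, presmooth = FALSE),
               rolling_ball_subtract(img, 10, presmooth = FALSE))
})

test_that("a small bright spot on dark background survives subtraction exactly", {
  img <- matrix(0, 128, 128)
  img[60:62, 70:72] <- 180
  # flat-disk variant: exact preservation (opening removes the whole spot)
  expect_equal(rolling_ball_subtract(img, 50, presmooth = FALSE), img)
  # spherical ball: a narrow spike deflects the ball surface by at most its
  # curvature over one pixel, so preservation is near-exact
  expect_equal(rolling_ball_subtract(img, 50), img, tolerance = 1e-3)
  expect_true(all(rolling_ball_subtract(img, 50)[img == 0] == 0))
})

test_that("flat-disk subtraction equals the brute-force opening oracle", {
  set.seed(33)
  for (rep in 1:10) {
    img <- random_image8(64, 64)
    got <- rolling_ball_subtract(img, 5, presmooth = FALSE)
    want <- img - oracle_disk_opening(img, 5)
    want[want < 0] <- 0
    expect_equal(got, want)
  }
})

test_that("rolling-ball output is bounded by the input and radius is validated", {
  set.seed(34)
  img <- random_image8(64, 64)
  out <- rolling_ball_subtract(img, 12)
  expect_true(all(out >= 0) && all(out <= img))
  expect_error(rolling_ball_subtract(img, 40), "half the image size")
  expect_error(rolling_ball_subtract(img, 0), "> 0")
})

test_that("contrast enhancement is a monotone percentile stretch", {
  # already spanning the full range with no saturation: unchanged
  img <- matrix(c(0, 255, 128, 64), 16, 16)
  expect_equal(enhance_contrast(img, 0), img)

  # linear ramp rescaled to span 0..255 (closed form)
  ramp <- matrix(rep(0:100, each = 10), 10, 101)
  en <- enhance_contrast(ramp, 0)
  expect_equal(en, round(ramp * 255 / 100))

  # monotone: enhanced order never contradicts input order
  set.seed(41)
  img <- random_image8(32, 32)
  en <- enhance_contrast(img, 0.05)
  o <- order(img)
  expect_true(all(diff(en[o]) >= 0))

  # degenerate rule: constant maps to zeros
  expect_equal(enhance_contrast(matrix(99, 8, 8), 0.05), matrix(0, 8, 8))
})

test_that("stack enhancement shares one map across planes", {
  set.seed(43)
  p1 <- random_image8(24, 24)
  p2 <- matrix(round(p1 / 4), 24, 24)  # dimmer plane
  en <- enhance_contrast_stack(list(p1, p2), 0)
  # the dim plane must not be amplified to full range on its own
  expect_lt(max(en[[2]]), 130)
  # pooled cuts applied identically: relative order across planes preserved
  expect_true(all(en[[2]] <= max(en[[1]])))
  # a single-plane stack reduces to plain enhancement
  expect_equal(enhance_contrast_stack(list(p1), 0.05)[[1]],
               enhance_contrast(p1, 0.05))
})

test_that("max projection is the pointwise maximum and order-invariant", {
  a <- matrix(0, 10, 10); a[3, 3] <- 100
  b <- matrix(0, 10, 10); b[7, 7] <- 150
  mp <- max_project(list(a, b))
  expect_equal(mp[3, 3], 100)
  expect_equal(mp[7, 7], 150)
  expect_equal(sum(mp > 0), 2)
  expect_equal(max_project(list(b, a)), mp)
  expect_equal(max_project(list(a)), a)
  expect_error(max_project(list()), "empty")
})

test_that("fixed threshold is inclusive at the threshold intensity", {
  expect_equal(sum(threshold_fixed(matrix(19, 8, 8), 20)), 0)
  img <- matrix(c(10, 20, 30), 3, 3)
  m <- threshold_fixed(img, 20)
  expect_equal(unclass(m), img >= 20, ignore_attr = TRUE)
  expect_equal(mask_area(m), 6)
})

test_that("bacteria segmentation finds each rendered bacterium", {
  # noiseless scene: segmented components = placed rods
  p <- synthetic_params(seed = 8, height = 192, width = 192, n_filaments = 1,
                        n_bacteria_on = 2, n_bacteria_off = 3, noise_sigma = 0)
  sc <- render_scene(p)
  mask <- segment_bacteria(sc$fov$fluorescence)
  n_comp <- max(EBImage::bwlabel(mask * 1))
  expect_equal(n_comp, 5)
  # every truth rod pixel is recovered
  expect_true(all(mask[sc$truth_bacteria_mask]))

  # with default noise, all substantial components are still the rods
  p2 <- synthetic_params(seed = 8, height = 192, width = 192, n_filaments = 1,
                         n_bacteria_on = 2, n_bacteria_off = 3)
  sc2 <- render_scene(p2)
  mask2 <- segment_bacteria(sc2$fov$fluorescence)
  lab <- EBImage::bwlabel(mask2 * 1)
  big <- sum(tabulate(lab[lab > 0]) >= 10)
  expect_equal(big, 5)
})

test_that("all-zero stacks give an empty mask", {
  stack <- list(matrix(0, 128, 128), matrix(0, 128, 128))
  expect_equal(mask_area(segment_bacteria(stack)), 0)
})

test_that("bacteria segmentation is 90-degree equivariant and plane-order invariant", {
  p <- synthetic_params(seed = 9, height = 128, width = 128, n_filaments = 1,
                        n_bacteria_on = 3, n_bacteria_off = 3)
  st <- render_scene(p)$fov$fluorescence
  m <- unclass(segment_bacteria(st))
  m_rot <- unclass(segment_bacteria(lapply(st, rot90)))
  expect_equal(m_rot, rot90(m), ignore_attr = TRUE)
  m_perm <- unclass(segment_bacteria(st[c(3, 1, 2)]))
  expect_equal(m_perm, m, ignore_attr = TRUE)
})

test_that("adding a constant background to every plane leaves the mask unchanged", {
  p <- synthetic_params(seed = 10, height = 128, width = 128, n_filaments = 1,
                        n_bacteria_on = 3, n_bacteria_off = 2,
                        bacterium_peak_intensity = 150)
  st <- render_scene(p)$fov$fluorescence
  shifted <- lapply(st, function(m) pmin(m + 25, 255))
  stopifnot(max(unlist(st)) <= 230)  # shift must not clip
  expect_equal(unclass(segment_bacteria(shifted)),
               unclass(segment_bacteria(st)))
})

test_that("bacteria mask area is non-increasing in the threshold", {
  p <- synthetic_params(seed = 12, height = 128, width = 128, n_filaments = 1,
                        n_bacteria_on = 3, n_bacteria_off = 3)
  st <- render_scene(p)$fov$fluorescence
  areas <- sapply(c(5, 20, 60, 150), function(t) {
    mask_area(segment_bacteria(st, pipeline_config(fixed_threshold = t)))
  })
  expect_true(all(diff(areas) <= 0))
})
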