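test_that("generation is a deterministic function of (spec, seed)", {
  spec <- tiny_spec()
  a <- generate_sample(spec, 7)
  b <- generate_sample(spec, 7)
  expect_identical(a, b)
  expect_false(identical(a$image, generate_sample(spec, 8)$image))
})

test_that("positive samples carry lung-interior opacities, negatives do not", {
  spec <- tiny_spec(64L)
  for (seed in 1:5) {
    s <- generate_sample(spec, seed, label = 1)
    expect_gte(length(s$lesions), 1)
    img <- s$image[, , 1]
    n <- spec$image_size
    xs <- (seq_len(n) - 0.5)
    lesion_px <- matrix(FALSE, n, n)
    for (l in s$lesions) {
      d2 <- outer((xs - l$center[2] * n)^2, rep(1, n)) +
        outer(rep(1, n), (xs - l$center[1] * n)^2)
      lesion_px <- lesion_px | (d2 <= l$radius^2)
      # lesion centers lie inside the lung mask
      ci <- ceiling(l$center[2] * n); cj <- ceiling(l$center[1] * n)
      expect_gt(s$lung_mask[ci, cj], 0)
    }
    lung <- s$lung_mask > 0
    expect_gt(mean(img[lesion_px & lung]), mean(img[lung & !lesion_px]))
  }
  for (seed in 1:10) {
    s <- generate_sample(spec, seed + 100, label = 0)
    img <- s$image[, , 1]
    expect_lte(max(img[s$lung_mask > 0]),
               spec$lung_intensity + 4 * spec$background_noise_sd)
  }
})

test_that("images stay in [0,1] after generation and every distortion", {
  spec <- tiny_spec()
  for (seed in 1:4) {
    s <- generate_sample(spec, seed)
    expect_true(all(s$image >= 0 & s$image <= 1))
    for (kind in c("crop_pad", "invert", "burned_text", "letterbox")) {
      d <- apply_distortion(s$image, kind, seed = seed)
      expect_identical(dim(d), dim(s$image))
      expect_true(all(d >= 0 & d <= 1))
    }
  }
})

test_that("mask area matches the analytic ellipse area within 2%", {
  spec <- phantom_spec(image_size = 128L)
  s <- generate_sample(spec, 1)
  analytic <- sum(vapply(spec$lung_ellipses,
                         function(e) pi * e$semi[1] * e$semi[2], numeric(1)))
  expect_lt(abs(mean(s$lung_mask) - analytic), 0.02)
})

test_that("a max-intensity threshold separates the classes at 95%+", {
  spec <- phantom_spec(image_size = 128L)
  n <- 200
  labs <- rep(c(0L, 1L), n / 2)
  stat <- vapply(seq_len(n), function(i) {
    s <- generate_sample(spec, i, label = labs[i])
    max(s$image[, , 1][s$lung_mask > 0])
  }, numeric(1))
  thr <- spec$lung_intensity + 4 * spec$background_noise_sd
  acc <- mean((stat > thr) == (labs == 1))
  expect_gte(acc, 0.95)
})

test_that("generate_dataset writes a consistent, reproducible manifest", {
  spec <- tiny_spec()
  d1 <- file.path(tempdir(), "ph-ds1")
  m1 <- generate_dataset(10, 0.5, spec, seed = 3, out_dir = d1)
  expect_equal(nrow(m1), 10)
  expect_equal(sum(m1$label), 5)
  expect_true(all(m1$split %in% c("train", "val", "test")))
  expect_true(all(file.exists(file.path(d1, m1$path))))
  expect_true(all(file.exists(file.path(d1, m1$mask_path))))

  m0 <- generate_dataset(3, 0, spec, seed = 3, out_dir = file.path(tempdir(), "ph-ds0"))
  expect_equal(sum(m0$label), 0)

  d2 <- file.path(tempdir(), "ph-ds2")
  m2 <- generate_dataset(10, 0.5, spec, seed = 3, out_dir = d2)
  attr(m2, "dir") <- attr(m1, "dir")
  expect_identical(m1, m2)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(file.path(d1, m1$path[i]), "raw", 1e6),
                     readBin(file.path(d2, m1$path[i]), "raw", 1e6))
  }
  expect_error(generate_dataset(1, 0.5, spec, 1, tempdir()), "n must be >= 2")
})

test_that("masks round-trip through 0/255 PNG with a 128 threshold", {
  ds <- shared_dataset()
  i <- 1L
  s <- generate_sample(ds$spec, seed = 42 * 131071 %% 2147483647 + i,
                       label = ds$manifest$label[i])
  mk <- png::readPNG(file.path(ds$dir, ds$manifest$mask_path[i]))
  expect_identical((mk >= 128 / 255) * 1L, s$lung_mask)
})

test_that("distortions behave as documented", {
  spec <- tiny_spec()
  img <- generate_sample(spec, 5)$image
  expect_equal(apply_distortion(apply_distortion(img, "invert"), "invert"), img)
  lb <- apply_distortion(img, "letterbox")
  band <- round(0.15 * dim(img)[1])
  expect_true(all(lb[seq_len(band), , ] == 0))
  expect_true(all(lb[seq(dim(img)[1] - band + 1, dim(img)[1]), , ] == 0))
  expect_identical(apply_distortion(img, "crop_pad", seed = 9),
                   apply_distortion(img, "crop_pad", seed = 9))
  bt <- apply_distortion(img, "burned_text", seed = 2)
  expect_gt(sum(bt == 1), 0)
  expect_error(apply_distortion(img, "sepia"), "unknown kind")
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(image_size = 64, lesion_radius_range = c(4, 50)),
               "exceeds the smallest lung semi-axis")
  expect_error(phantom_spec(lesion_contrast = 0.01),
               "lesion_contrast")
  expect_error(
    phantom_spec(lung_ellipses = list(
      list(center = c(0.1, 0.5), semi = c(0.3, 0.2)),
      list(center = c(0.7, 0.5), semi = c(0.1, 0.2)))),
    "outside the image frame")
})
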