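# Shared fixture: one synthetic pair at modest size keeps this file fast.
reg_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_registration_pair(seed = 3, rotation_deg = 10,
                                           scale = 1.1, shift_px = c(30, -20),
                                           image_px = 384, n_cells = 150)
    }
    cache
  }
})

test_that("preprocessing controls downscale factor, channels and inversion", {
  big <- pixel_image(matrix(runif(300 * 200), 300, 200), 1)
  p <- preprocess_for_features(big, cap = 150)
  expect_identical(p$factor, 2L)
  expect_identical(dim(p$img), c(150L, 100L))
  p1 <- preprocess_for_features(big, cap = 4096)
  expect_identical(p1$factor, 1L)
  expect_identical(dim(p1$img), c(300L, 200L))
  # RGB luminance collapses to one channel; inversion flips contrast
  rgb <- pixel_image(array(runif(60 * 60 * 3), c(60, 60, 3)), 1)
  pr <- preprocess_for_features(rgb)
  expect_identical(length(dim(pr$img)), 2L)
  pi_ <- preprocess_for_features(big, invert = TRUE)
  expect_equal(pi_$img, round((1 - p1$img) * 255) / 255, tolerance = 1e-3)
  # constant image stays valid and yields zero keypoints downstream
  flat <- preprocess_for_features(pixel_image(matrix(5, 64, 64), 1))
  expect_true(all(flat$img == 0))
  expect_identical(nrow(detect_and_describe(flat$img)$keypoints), 0L)
})

test_that("the synthetic nuclei image yields abundant keypoints", {
  p <- preprocess_for_features(reg_pair()$fixed)
  f <- detect_and_describe(p$img)
  expect_gte(nrow(f$keypoints), 50L)
  expect_identical(ncol(f$descriptors), 128L)
  # descriptors are non-negative and unit-normalized
  expect_true(all(f$descriptors >= 0))
  nrm <- sqrt(rowSums(f$descriptors^2))
  expect_true(all(abs(nrm - 1) < 1e-6))
})

test_that("descriptors match across a 90-degree rotation", {
  p <- preprocess_for_features(reg_pair()$fixed)
  rot <- t(p$img)[, nrow(p$img):1]
  fa <- detect_and_describe(p$img)
  fb <- detect_and_describe(rot)
  m <- match_descriptors(fa$descriptors, fb$descriptors, ratio = 0.75)
  expect_gte(nrow(m) / nrow(fa$keypoints), 0.3)
})

test_that("matching is exact on identical sets, empty on noise, monotone in ratio", {
  p <- preprocess_for_features(reg_pair()$fixed)
  f <- detect_and_describe(p$img)
  m <- match_descriptors(f$descriptors, f$descriptors, ratio = 0.9)
  expect_identical(m$idx_a, m$idx_b)
  expect_true(all(m$distance < 1e-6))
  # disjoint random descriptors survive the ratio test almost never
  set.seed(1)
  ra <- matrix(runif(100 * 128), 100); ra <- ra / sqrt(rowSums(ra^2))
  rb <- matrix(runif(100 * 128), 100); rb <- rb / sqrt(rowSums(rb^2))
  expect_lte(nrow(match_descriptors(ra, rb, ratio = 0.75)), 2L)
  # monotonicity
  n075 <- nrow(match_descriptors(f$descriptors, f$descriptors, ratio = 0.75))
  n100 <- nrow(match_descriptors(f$descriptors, f$descriptors, ratio = 1.0))
  expect_gte(n100, n075)
  # fewer than 2 candidates: no match possible
  expect_identical(nrow(match_descriptors(ra, rb[1, , drop = FALSE])), 0L)
})

test_that("RANSAC recovers a planted affine exactly and resists outliers", {
  set.seed(2)
  A <- rbind(c(1.05, -0.1, 12), c(0.08, 0.95, -7), c(0, 0, 1))
  src <- cbind(runif(60, 0, 500), runif(60, 0, 500))
  dst <- transform_points(src, A)
  res <- estimate_transform(src, dst, "affine")
  expect_lt(mean_corner_error(res$transform, A, 500, 500), 1e-3)
  expect_identical(res$n_inliers, 60L)
  # 30% uniform outliers
  n_out <- 26L
  dst_bad <- rbind(dst, cbind(runif(n_out, 0, 500), runif(n_out, 0, 500)))
  src_all <- rbind(src, cbind(runif(n_out, 0, 500), runif(n_out, 0, 500)))
  res2 <- estimate_transform(src_all, dst_bad, "affine")
  expect_lt(mean_corner_error(res2$transform, A, 500, 500), 1)
  expect_lte(res2$n_inliers, 60L + 2L)  # outliers excluded (chance hits aside)
  expect_error(estimate_transform(src[1:2, ], dst[1:2, ], "affine"),
               "registration failed")
})

test_that("RANSAC inlier count is non-increasing as the threshold shrinks", {
  set.seed(8)
  A <- rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1))
  src <- cbind(runif(80, 0, 300), runif(80, 0, 300))
  dst <- transform_points(src, A) + matrix(rnorm(160, 0, 2), ncol = 2)
  counts <- vapply(c(8, 4, 2, 1), function(th) {
    set.seed(11)
    estimate_transform(src, dst, "affine", ransac_threshold = th)$n_inliers
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("perspective estimation recovers a planted homography", {
  set.seed(4)
  H <- rbind(c(1.02, 0.03, 8), c(-0.02, 0.98, -5), c(1e-5, -2e-5, 1))
  src <- cbind(runif(50, 0, 400), runif(50, 0, 400))
  dst <- transform_points(src, H)
  res <- estimate_transform(src, dst, "perspective")
  expect_lt(mean_corner_error(res$transform, H, 400, 400), 0.01)
})

test_that("transform_points agrees with per-point matrix algebra and inverts", {
  expect_equal(transform_points(rbind(c(0, 0)), diag(3)), rbind(c(0, 0)))
  Tr <- rbind(c(1, 0, 5), c(0, 1, 7), c(0, 0, 1))
  expect_equal(transform_points(rbind(c(0, 0)), Tr), rbind(c(5, 7)))
  set.seed(5)
  A <- rbind(c(0.9, 0.2, 3), c(-0.3, 1.1, -2), c(0, 0, 1))
  pts <- matrix(runif(40, -50, 50), ncol = 2)
  manual <- t(apply(pts, 1, function(p) (A %*% c(p, 1))[1:2]))
  expect_equal(transform_points(pts, A), manual, tolerance = 1e-12)
  back <- transform_points(transform_points(pts, A), solve(A))
  expect_equal(back, pts, tolerance = 1e-6)
})

test_that("self-registration is near-identity", {
  res <- register_pair(reg_pair()$fixed, reg_pair()$fixed)
  expect_lt(mean_corner_error(res$transform, diag(3), 384, 384), 0.5)
  expect_equal(res$transform[3, ], c(0, 0, 1))
})

test_that("a planted similarity transform is recovered below 2 px", {
  pr <- reg_pair()
  res <- register_pair(pr$fixed, pr$moving)
  expect_lt(mean_corner_error(res$transform, pr$transform, 384, 384), 2)
  expect_gte(res$n_inliers, 8L)
  expect_false(res$flagged)
  qc <- glance(res)
  expect_identical(qc$n_matches, res$n_matches)
  expect_lte(qc$n_inliers, qc$n_matches)
  expect_gte(qc$mean_reprojection_error, 0)
})

test_that("unrelated images fail or come back flagged", {
  other <- generate_registration_pair(seed = 4, image_px = 384,
                                      n_cells = 150)$fixed
  res <- tryCatch(suppressWarnings(register_pair(reg_pair()$fixed, other)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "registration failed")
  } else {
    expect_true(res$flagged || res$n_inliers / res$n_matches < 0.2)
  }
})

test_that("image warping is exact for identity and shifts content", {
  img <- reg_pair()$fixed
  id <- apply_transform_image(img, diag(3), img_shape(img)[1:2])
  expect_equal(img_pixels(id), img_pixels(img), tolerance = 1e-12)
  Tr <- rbind(c(1, 0, 10), c(0, 1, 0), c(0, 0, 1))
  sh <- apply_transform_image(img, Tr, img_shape(img)[1:2])
  px <- img_pixels(sh)
  expect_true(all(px[, 1:10] == 0))
  expect_equal(px[, 11:384], img_pixels(img)[, 1:374], tolerance = 1e-9)
  expect_error(apply_transform_image(img, matrix(0, 3, 3), c(10, 10)),
               "singular")
})

test_that("warping by a transform then its inverse preserves the interior", {
  pr <- reg_pair()
  fwd <- apply_transform_image(pr$fixed, pr$transform, c(384, 384))
  back <- apply_transform_image(fwd, solve(pr$transform), c(384, 384))
  a <- img_pixels(pr$fixed)[100:284, 100:284]
  b <- img_pixels(back)[100:284, 100:284]
  ncc <- stats::cor(as.vector(a), as.vector(b))
  expect_gte(ncc, 0.98)
})
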