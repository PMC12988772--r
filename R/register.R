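#' Robust transform estimation and image registration
#'
#' [register_pair()] aligns a moving image (typically a post-run
#' histological staining) to a fixed image (the run's nuclear fluorescence
#' image, already registered to the omics data): both images are
#' preprocessed, scale-invariant keypoints are detected and described,
#' descriptors are matched with a ratio test, and a RANSAC loop fits an
#' affine (default) or perspective 3 x 3 transform mapping moving
#' full-resolution pixel coordinates into the fixed full-resolution pixel
#' frame. The result carries quality-control metrics: keypoint, match and
#' inlier counts, the inlier fraction and the mean reprojection error over
#' inliers.
#'
#' Pixel coordinates are 0-based with x along columns and y along rows,
#' so pixel (r, c) of a matrix sits at (x, y) = (c - 1, r - 1).
#'
#' @name registration
NULL

new_registration_result <- function(transform, kind, qc) {
  stopifnot(is.matrix(transform), all(dim(transform) == c(3L, 3L)))
  if (kind == "affine" &&
      max(abs(transform[3L, ] - c(0, 0, 1))) > 1e-12) {
    stop("affine transform must have last row (0, 0, 1)", call. = FALSE)
  }
  structure(c(list(transform = transform, kind = kind), qc),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result %s>\n",
                     "  keypoints: %d fixed / %d moving\n",
                     "  matches: %d, inliers: %d (%.2f)\n",
                     "  mean reprojection error: %.3f px\n"),
              x$kind, x$n_keypoints_fixed %||% NA, x$n_keypoints_moving %||% NA,
              x$n_matches, x$n_inliers,
              x$n_inliers / max(1L, x$n_matches),
              x$mean_reprojection_error))
  print(round(x$transform, 6))
  invisible(x)
}

#' Estimate a transform from point correspondences with RANSAC
#'
#' Repeated minimal samples (3 for affine, 4 for perspective) propose
#' candidate transforms; the consensus set under the reprojection
#' threshold selects the best, which is refit by least squares on its
#' inliers. Randomness comes from R's RNG — seed for reproducibility.
#'
#' @param src n x 2 matrix of source (moving) points.
#' @param dst n x 2 matrix of destination (fixed) points, row-matched.
#' @param kind `"affine"` or `"perspective"`.
#' @param ransac_threshold inlier reprojection threshold in pixels.
#' @param max_iter RANSAC iterations.
#' @return A `registration_result` with the fitted transform, inlier
#'   count and mean reprojection error over inliers.
#' @export
estimate_transform <- function(src, dst, kind = c("affine", "perspective"),
                               ransac_threshold = 5, max_iter = 2000L) {
  kind <- match.arg(kind)
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  need <- if (kind == "affine") 3L else 4L
  if (n < need) {
    stop(sprintf("registration failed: %d matches, %d needed for %s",
                 n, need, kind), call. = FALSE)
  }
  fit_fun <- if (kind == "affine") fit_affine else fit_homography
  best_inliers <- NULL
  for (it in seq_len(max_iter)) {
    pick <- sample.int(n, need)
    Tc <- tryCatch(fit_fun(src[pick, , drop = FALSE],
                           dst[pick, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Tc)) next
    e <- reprojection_errors(src, dst, Tc)
    inl <- which(e < ransac_threshold)
    if (length(inl) > length(best_inliers)) best_inliers <- inl
  }
  if (length(best_inliers) < need) {
    stop(sprintf("registration failed: no consensus among %d matches", n),
         call. = FALSE)
  }
  Tbest <- fit_fun(src[best_inliers, , drop = FALSE],
                   dst[best_inliers, , drop = FALSE])
  e <- reprojection_errors(src, dst, Tbest)
  inl <- which(e < ransac_threshold)
  new_registration_result(
    Tbest, kind,
    list(n_matches = n, n_inliers = length(inl),
         mean_reprojection_error = mean(e[inl]),
         downscale_factor = 1L))
}

fit_affine <- function(src, dst) {
  A <- cbind(src, 1)
  # least squares for >= 3 points, exact for 3
  coef <- qr.solve(A, dst)
  if (any(!is.finite(coef))) stop("degenerate sample", call. = FALSE)
  rbind(t(coef), c(0, 0, 1))
}

fit_homography <- function(src, dst) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2L, ctr)^2)))
    Tn <- rbind(c(sc, 0, -sc * ctr[1L]), c(0, sc, -sc * ctr[2L]), c(0, 0, 1))
    list(T = Tn, p = sweep(p, 2L, ctr) * sc)
  }
  a <- norm_pts(src); b <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- a$p[i, 1L]; y <- a$p[i, 2L]; u <- b$p[i, 1L]; v <- b$p[i, 2L]
    A[2L * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2L * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nv = 9L)$v[, 9L]
  H <- matrix(h, 3L, 3L, byrow = TRUE)
  H <- solve(b$T) %*% H %*% a$T
  if (abs(H[3L, 3L]) < 1e-12) stop("degenerate sample", call. = FALSE)
  H / H[3L, 3L]
}

reprojection_errors <- function(src, dst, transform) {
  p <- transform_points(src, transform)
  sqrt(rowSums((p - dst)^2))
}

#' Apply a 3 x 3 transform to points
#'
#' Homogeneous application followed by dehomogenization. Points whose
#' homogeneous w collapses to ~0 under a perspective transform are flagged
#' invalid (NA) with a warning.
#'
#' @param points n x 2 matrix.
#' @param transform 3 x 3 matrix.
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(points, transform) {
  points <- matrix(as.numeric(as.matrix(points)), ncol = 2L)
  ph <- cbind(points, 1) %*% t(transform)
  w <- ph[, 3L]
  bad <- abs(w) < 1e-12
  if (any(bad)) {
    warning(sprintf("%d point(s) invalid after perspective division",
                    sum(bad)), call. = FALSE)
    w[bad] <- NA_real_
  }
  ph[, 1:2, drop = FALSE] / w
}

#' Register a moving image onto a fixed image
#'
#' Full pipeline: preprocess, detect and describe keypoints, ratio-test
#' matching, RANSAC fit, transform rescaled to full resolution. Any stage
#' yielding too little signal raises a registration-failed error naming
#' the stage and its counts; a successful fit with inlier fraction below
#' `flag_inlier_fraction` is returned but flagged (`$flagged`), with a
#' warning — low consensus usually means the images are unrelated.
#'
#' @param fixed,moving `pixel_image`s (fixed: nuclear fluorescence;
#'   moving: e.g. post-run histology).
#' @param kind `"affine"` (default; flat sections need no more) or
#'   `"perspective"`.
#' @param invert_moving invert the moving image's intensities before
#'   detection (TRUE for bright-field histology).
#' @param cap downscale cap for feature detection, px.
#' @param ratio Lowe ratio for matching.
#' @param ransac_threshold RANSAC reprojection threshold in (downscaled)
#'   pixels.
#' @param flag_inlier_fraction QC flag threshold on the inlier fraction.
#' @param flag_min_inliers QC flag threshold on the inlier count: a tiny
#'   consensus (an affine fits any 3 points) is not evidence of alignment.
#' @return A `registration_result` whose `transform` maps moving
#'   full-resolution pixel coordinates to fixed full-resolution pixel
#'   coordinates.
#' @export
register_pair <- function(fixed, moving, kind = c("affine", "perspective"),
                          invert_moving = FALSE, cap = 4096L, ratio = 0.75,
                          ransac_threshold = 5, flag_inlier_fraction = 0.2,
                          flag_min_inliers = 8L) {
  kind <- match.arg(kind)
  pf <- preprocess_for_features(fixed, cap = cap)
  pm <- preprocess_for_features(moving, invert = invert_moving, cap = cap)
  ff <- detect_and_describe(pf$img)
  fm <- detect_and_describe(pm$img)
  nf <- nrow(ff$keypoints); nm <- nrow(fm$keypoints)
  if (nf < 3L || nm < 3L) {
    stop(sprintf("registration failed at detection: %d fixed / %d moving keypoints",
                 nf, nm), call. = FALSE)
  }
  matches <- match_descriptors(fm$descriptors, ff$descriptors, ratio = ratio)
  need <- if (kind == "affine") 3L else 4L
  if (nrow(matches) < need) {
    stop(sprintf("registration failed at matching: %d match(es) from %d/%d keypoints",
                 nrow(matches), nf, nm), call. = FALSE)
  }
  src <- as.matrix(fm$keypoints[matches$idx_a, c("x", "y")])
  dst <- as.matrix(ff$keypoints[matches$idx_b, c("x", "y")])
  res <- estimate_transform(src, dst, kind = kind,
                            ransac_threshold = ransac_threshold)
  # rescale: detection frames are downscaled by integer factors
  Sf <- diag(c(pf$factor, pf$factor, 1))
  Sm <- diag(c(pm$factor, pm$factor, 1))
  res$transform <- Sf %*% res$transform %*% solve(Sm)
  if (res$kind == "affine") res$transform[3L, ] <- c(0, 0, 1)
  res$mean_reprojection_error <- res$mean_reprojection_error * pf$factor
  res$n_keypoints_fixed <- nf
  res$n_keypoints_moving <- nm
  res$downscale_factor <- max(pf$factor, pm$factor)
  frac <- res$n_inliers / res$n_matches
  res$flagged <- frac < flag_inlier_fraction ||
    res$n_inliers < flag_min_inliers
  if (res$flagged) {
    warning(sprintf(
      "low consensus (%d inliers, fraction %.2f): registration is unreliable",
      res$n_inliers, frac), call. = FALSE)
  }
  res
}

#' Resample a moving image into the fixed frame
#'
#' Inverse-mapping bilinear resampling: output pixel (r, c) takes the
#' moving image's value at `transform^-1 (c-1, r-1)`; samples falling
#' outside the moving image are 0.
#'
#' @param moving a `pixel_image` (single channel or channels resampled
#'   independently).
#' @param transform 3 x 3 matrix mapping moving pixel coordinates to
#'   fixed pixel coordinates (as from [register_pair()]).
#' @param output_shape integer `c(h, w)` of the fixed frame.
#' @return A `pixel_image` in the fixed frame (pixel size of the moving
#'   image preserved as metadata).
#' @export
apply_transform_image <- function(moving, transform, output_shape) {
  if (abs(det(transform)) < 1e-12) {
    stop("singular transform", call. = FALSE)
  }
  Ti <- solve(transform)
  h <- as.integer(output_shape[1L]); w <- as.integer(output_shape[2L])
  xs <- rep(0:(w - 1L), each = h)
  ys <- rep(0:(h - 1L), times = w)
  sp <- transform_points(cbind(xs, ys), Ti)
  px <- img_pixels(moving)
  nch <- img_n_channels(moving)
  sample_one <- function(mat) {
    nr <- nrow(mat); ncl <- ncol(mat)
    x <- sp[, 1L]; y <- sp[, 2L]
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    v <- numeric(length(x))
    gather <- function(yy, xx) {
      ok <- yy >= 0 & yy <= nr - 1L & xx >= 0 & xx <= ncl - 1L
      out <- numeric(length(xx))
      out[ok] <- mat[cbind(yy[ok] + 1L, xx[ok] + 1L)]
      out
    }
    v <- gather(y0, x0) * (1 - fx) * (1 - fy) +
      gather(y0, x0 + 1) * fx * (1 - fy) +
      gather(y0 + 1, x0) * (1 - fx) * fy +
      gather(y0 + 1, x0 + 1) * fx * fy
    matrix(v, nrow = h, ncol = w)
  }
  out <- if (nch == 1L) {
    sample_one(if (length(dim(px)) == 3L) px[, , 1L] else px)
  } else {
    array(vapply(seq_len(nch), function(ch) sample_one(px[, , ch]),
                 matrix(0, h, w)), dim = c(h, w, nch))
  }
  pixel_image(out, moving$pixel_size, channel_names = moving$channel_names,
              name = paste0(moving$name, "_registered"))
}

# Mean displacement of the image corners between two transforms, px.
mean_corner_error <- function(t_est, t_true, width, height) {
  corners <- rbind(c(0, 0), c(width - 1, 0), c(width - 1, height - 1),
                   c(0, height - 1))
  a <- transform_points(corners, t_est)
  b <- transform_points(corners, t_true)
  mean(sqrt(rowSums((a - b)^2)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a registration result into one row per transform entry
#' @param x a `registration_result`.
#' @param ... unused.
#' @method tidy registration_result
#' @export
tidy.registration_result <- function(x, ...) {
  tibble::tibble(row = rep(1:3, each = 3L), col = rep(1:3, times = 3L),
                 value = as.vector(t(x$transform)))
}

#' One-row QC summary of a registration result
#' @param x a `registration_result`.
#' @param ... unused.
#' @method glance registration_result
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_keypoints_fixed = x$n_keypoints_fixed %||% NA_integer_,
                 n_keypoints_moving = x$n_keypoints_moving %||% NA_integer_,
                 n_matches = x$n_matches, n_inliers = x$n_inliers,
                 inlier_fraction = x$n_inliers / max(1L, x$n_matches),
                 mean_reprojection_error = x$mean_reprojection_error,
                 downscale_factor = x$downscale_factor,
                 flagged = isTRUE(x$flagged))
}
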