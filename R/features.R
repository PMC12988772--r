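#' Preprocess an image for feature detection
#'
#' Converts to a single grayscale channel (luminance for RGB), optionally
#' inverts intensities — bright-field histology has dark nuclei on a light
#' background, while fluorescence has bright nuclei, and the detector
#' needs both modalities to agree — downscales by the smallest integer
#' factor bringing the largest dimension under `cap`, and stretches the
#' contrast to the full 8-bit range.
#'
#' @param image a `pixel_image`.
#' @param invert invert intensities (use for bright-field histology)?
#' @param cap maximum allowed image dimension after downscaling, px.
#' @return List with `img` (matrix in \[0, 1\], 8-bit quantized) and
#'   `factor` (integer downscale factor).
#' @export
preprocess_for_features <- function(image, invert = FALSE, cap = 4096L) {
  px <- img_pixels(image)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] >= 3L) {
      px <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
    } else {
      px <- px[, , 1L]
    }
  }
  f <- max(1L, as.integer(ceiling(max(dim(px)) / cap)))
  if (f > 1L) {
    px <- EBImage::resize(px, w = floor(nrow(px) / f), h = floor(ncol(px) / f))
  }
  rng <- range(px)
  if (rng[2L] > rng[1L]) {
    px <- (px - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    px <- px * 0
  }
  if (invert) px <- 1 - px
  px <- round(px * 255) / 255
  list(img = px, factor = f)
}

#' Detect scale-invariant keypoints and compute 128-d descriptors
#'
#' A difference-of-Gaussians scale-space detector with gradient-orientation
#' descriptors in the SIFT construction: Gaussian octaves (3 scales per
#' octave, base sigma 1.6), 26-neighbour extrema with contrast and
#' edge-response rejection, per-axis parabolic sub-pixel refinement, a
#' 36-bin orientation histogram assigning up to two dominant orientations,
#' and a 4 x 4 x 8 trilinearly-binned gradient histogram descriptor
#' (normalized, clipped at 0.2, renormalized).
#'
#' Keypoint coordinates are 0-based pixel positions (x along columns, y
#' along rows) in the frame of the supplied image.
#'
#' @param img8 single-channel matrix in \[0, 1\] from
#'   [preprocess_for_features()].
#' @param contrast_thresh minimum absolute difference-of-Gaussians
#'   response.
#' @param edge_thresh principal-curvature ratio limit (Hessian test).
#' @param max_keypoints keep at most this many, strongest first.
#' @return List with `keypoints` (tibble: x, y, sigma, angle, response)
#'   and `descriptors` (n x 128 matrix); zero rows for featureless images.
#' @export
detect_and_describe <- function(img8, contrast_thresh = 0.0133,
                                edge_thresh = 10, max_keypoints = 1500L) {
  empty <- list(keypoints = tibble::tibble(x = numeric(), y = numeric(),
                                           sigma = numeric(),
                                           angle = numeric(),
                                           response = numeric()),
                descriptors = matrix(numeric(0), 0L, 128L))
  if (min(dim(img8)) < 32L || max(img8) == min(img8)) return(empty)

  ss <- build_scale_space(img8)
  kp <- list(); desc <- list()
  for (o in seq_along(ss$octaves)) {
    oct <- ss$octaves[[o]]
    grads <- lapply(oct$gauss, image_gradients)
    for (mid in 2:3) {  # middle DoG indices with both neighbours
      cand <- dog_extrema(oct$dog[[mid - 1L]], oct$dog[[mid]],
                          oct$dog[[mid + 1L]], contrast_thresh, edge_thresh)
      if (nrow(cand) == 0L) next
      sigma_rel <- ss$sigma0 * 2^((mid - 1) / ss$n_split)
      res <- orient_and_describe(cand, grads[[mid]], sigma_rel)
      if (nrow(res$kp) == 0L) next
      scale_mult <- 2^(o - 1L)
      res$kp$x <- res$kp$x * scale_mult
      res$kp$y <- res$kp$y * scale_mult
      res$kp$sigma <- sigma_rel * scale_mult
      kp[[length(kp) + 1L]] <- res$kp
      desc[[length(desc) + 1L]] <- res$desc
    }
  }
  if (length(kp) == 0L) return(empty)
  keypoints <- dplyr::bind_rows(kp)
  descriptors <- do.call(rbind, desc)
  ord <- order(-abs(keypoints$response))
  if (length(ord) > max_keypoints) ord <- ord[seq_len(max_keypoints)]
  list(keypoints = keypoints[ord, , drop = FALSE],
       descriptors = descriptors[ord, , drop = FALSE])
}

# Gaussian scale space: octaves of 6 Gaussian levels (incremental blurs),
# 5 DoG levels each; next octave decimates the 2*sigma0 level.
build_scale_space <- function(img, n_split = 3L, sigma0 = 1.6,
                              init_blur = 0.5) {
  k <- 2^(1 / n_split)
  base <- EBImage::gblur(img, sigma = sqrt(sigma0^2 - init_blur^2))
  octaves <- list()
  repeat {
    gauss <- vector("list", n_split + 3L)
    gauss[[1L]] <- base
    sig_prev <- sigma0
    for (i in 2:(n_split + 3L)) {
      sig_i <- sigma0 * k^(i - 1)
      gauss[[i]] <- EBImage::gblur(gauss[[i - 1L]],
                                   sigma = sqrt(sig_i^2 - sig_prev^2))
      sig_prev <- sig_i
    }
    dog <- lapply(1:(n_split + 2L), function(i) gauss[[i + 1L]] - gauss[[i]])
    octaves[[length(octaves) + 1L]] <- list(gauss = gauss, dog = dog)
    nxt <- gauss[[n_split + 1L]]  # sigma = 2 * sigma0
    base <- nxt[seq(1L, nrow(nxt), by = 2L), seq(1L, ncol(nxt), by = 2L)]
    # the largest blur kernel must still fit the octave
    if (min(dim(base)) < 32L) break
  }
  list(octaves = octaves, sigma0 = sigma0, n_split = n_split)
}

# 26-neighbour extrema of the middle DoG plane with contrast, edge and
# sub-pixel tests. Returns tibble(r, c, x, y, response) in octave pixels
# (x, y 0-based, sub-pixel refined).
dog_extrema <- function(below, mid, above, contrast_thresh, edge_thresh) {
  nr <- nrow(mid); nc <- ncol(mid)
  rs <- 2:(nr - 1L); cs <- 2:(nc - 1L)
  ctr <- mid[rs, cs]
  mx <- NULL; mn <- NULL
  planes <- list(below, mid, above)
  for (pi in 1:3) {
    plane <- planes[[pi]]
    for (dr in -1:1) for (dc in -1:1) {
      if (pi == 2L && dr == 0L && dc == 0L) next
      nb <- plane[rs + dr, cs + dc]
      mx <- if (is.null(mx)) nb else pmax(mx, nb)
      mn <- if (is.null(mn)) nb else pmin(mn, nb)
    }
  }
  is_ext <- (ctr > mx | ctr < mn) & abs(ctr) > contrast_thresh
  idx <- which(is_ext)
  if (length(idx) == 0L) {
    return(tibble::tibble(r = integer(), c = integer(), x = numeric(),
                          y = numeric(), response = numeric()))
  }
  r <- rs[((idx - 1L) %% length(rs)) + 1L]
  c <- cs[((idx - 1L) %/% length(rs)) + 1L]
  # edge response: principal curvature ratio of the 2x2 Hessian
  i0 <- (c - 1L) * nr + r  # linear index of (r, c)
  dxx <- mid[i0 + nr] + mid[i0 - nr] - 2 * mid[i0]
  dyy <- mid[i0 + 1L] + mid[i0 - 1L] - 2 * mid[i0]
  dxy <- (mid[i0 + nr + 1L] + mid[i0 - nr - 1L] -
            mid[i0 + nr - 1L] - mid[i0 - nr + 1L]) / 4
  tr <- dxx + dyy; det <- dxx * dyy - dxy^2
  keep <- det > 0 & tr^2 / det < (edge_thresh + 1)^2 / edge_thresh
  r <- r[keep]; c <- c[keep]; i0 <- i0[keep]
  if (length(r) == 0L) {
    return(tibble::tibble(r = integer(), c = integer(), x = numeric(),
                          y = numeric(), response = numeric()))
  }
  # per-axis parabolic sub-pixel offset, clamped to half a pixel
  para <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    off <- ifelse(abs(den) > 1e-12, 0.5 * (fm - fp) / den, 0)
    pmax(pmin(off, 0.5), -0.5)
  }
  off_c <- para(mid[i0 - nr], mid[i0], mid[i0 + nr])
  off_r <- para(mid[i0 - 1L], mid[i0], mid[i0 + 1L])
  tibble::tibble(r = r, c = c,
                 x = (c - 1L) + off_c, y = (r - 1L) + off_r,
                 response = mid[i0])
}

image_gradients <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  dx <- matrix(0, nr, nc); dy <- matrix(0, nr, nc)
  dx[, 2:(nc - 1L)] <- (g[, 3:nc] - g[, 1:(nc - 2L)]) / 2
  dy[2:(nr - 1L), ] <- (g[3:nr, ] - g[1:(nr - 2L), ]) / 2
  list(mag = sqrt(dx^2 + dy^2), ang = atan2(dy, dx))
}

# Assign up to two dominant orientations per keypoint and build the
# 4x4x8 descriptor. `grad` holds gradient magnitude/angle of the Gaussian
# level the keypoint was found on; sigma_rel is its within-octave scale.
orient_and_describe <- function(cand, grad, sigma_rel) {
  nr <- nrow(grad$mag); nc <- ncol(grad$mag)
  n_bins <- 36L
  sig_ori <- 1.5 * sigma_rel
  rad_o <- as.integer(round(3 * sig_ori))
  d <- 4L; n_ori <- 8L
  hist_width <- 3 * sigma_rel
  rad_d <- as.integer(round(hist_width * sqrt(2) * (d + 1) * 0.5))

  off <- expand.grid(dr = -rad_o:rad_o, dc = -rad_o:rad_o)
  w_o <- exp(-(off$dr^2 + off$dc^2) / (2 * sig_ori^2))
  offd <- expand.grid(dr = -rad_d:rad_d, dc = -rad_d:rad_d)

  kps <- list(); descs <- list()
  for (i in seq_len(nrow(cand))) {
    r0 <- cand$r[i]; c0 <- cand$c[i]
    if (r0 - rad_d < 1L || r0 + rad_d > nr || c0 - rad_d < 1L ||
        c0 + rad_d > nc) next
    # orientation histogram
    ro <- r0 + off$dr; co <- c0 + off$dc
    ok <- ro >= 1L & ro <= nr & co >= 1L & co <= nc
    li <- (co[ok] - 1L) * nr + ro[ok]
    m <- grad$mag[li]; a <- grad$ang[li]
    bins <- (floor(a / (2 * pi) * n_bins) %% n_bins) + 1L
    h <- numeric(n_bins)
    acc <- rowsum((m * w_o[ok]), bins)
    h[as.integer(rownames(acc))] <- acc[, 1L]
    for (s in 1:2) {  # circular smoothing
      h <- (c(h[n_bins], h[-n_bins]) + h + c(h[-1L], h[1L])) / 3
    }
    pk <- which(h >= 0.8 * max(h) &
                  h > c(h[n_bins], h[-n_bins]) & h >= c(h[-1L], h[1L]))
    if (length(pk) == 0L) pk <- which.max(h)
    if (length(pk) > 2L) pk <- pk[order(-h[pk])][1:2]
    for (p in pk) {
      # parabolic peak interpolation on the circular histogram
      hl <- h[if (p == 1L) n_bins else p - 1L]
      hr <- h[if (p == n_bins) 1L else p + 1L]
      den <- hl - 2 * h[p] + hr
      dp <- if (abs(den) > 1e-12) 0.5 * (hl - hr) / den else 0
      theta <- ((p - 1 + dp + 0.5) / n_bins) * 2 * pi
      dsc <- sift_descriptor(r0, c0, theta, grad, offd, hist_width, d,
                             n_ori, nr, nc)
      kps[[length(kps) + 1L]] <- c(x = c0 - 1L + (cand$x[i] - (c0 - 1L)),
                                   y = r0 - 1L + (cand$y[i] - (r0 - 1L)),
                                   angle = theta, response = cand$response[i])
      descs[[length(descs) + 1L]] <- dsc
    }
  }
  if (length(kps) == 0L) {
    return(list(kp = tibble::tibble(x = numeric(), y = numeric(),
                                    sigma = numeric(), angle = numeric(),
                                    response = numeric()),
                desc = matrix(numeric(0), 0L, 128L)))
  }
  km <- do.call(rbind, kps)
  list(kp = tibble::tibble(x = km[, "x"], y = km[, "y"], sigma = NA_real_,
                           angle = km[, "angle"],
                           response = km[, "response"]),
       desc = do.call(rbind, descs))
}

sift_descriptor <- function(r0, c0, theta, grad, offd, hist_width, d,
                            n_ori, nr, nc) {
  ct <- cos(theta); st <- sin(theta)
  dx <- offd$dc; dy <- offd$dr      # x along columns, y along rows
  # rotate into the keypoint frame
  xr <- ( ct * dx + st * dy) / hist_width
  yr <- (-st * dx + ct * dy) / hist_width
  rbin <- yr + d / 2 - 0.5
  cbin <- xr + d / 2 - 0.5
  ok <- rbin > -1 & rbin < d & cbin > -1 & cbin < d
  li <- (c0 + dx[ok] - 1L) * nr + (r0 + dy[ok])
  m <- grad$mag[li]
  a <- grad$ang[li] - theta
  obin <- (a / (2 * pi)) * n_ori
  obin <- obin %% n_ori
  w <- exp(-(xr[ok]^2 + yr[ok]^2) / (2 * (0.5 * d)^2)) * m
  rb <- rbin[ok]; cb <- cbin[ok]
  r_f <- floor(rb); c_f <- floor(cb); o_f <- floor(obin)
  dr <- rb - r_f; dc <- cb - c_f; do_ <- obin - o_f
  vec <- numeric((d + 2L) * (d + 2L) * n_ori)
  dim(vec) <- c(d + 2L, d + 2L, n_ori)
  for (ir in 0:1) for (ic in 0:1) for (io in 0:1) {
    wt <- w * (if (ir) dr else 1 - dr) * (if (ic) dc else 1 - dc) *
      (if (io) do_ else 1 - do_)
    rr <- r_f + ir + 2L  # +2: shift (-1-based) into 1-based padded array
    cc <- c_f + ic + 2L
    oo <- ((o_f + io) %% n_ori) + 1L
    idx <- (oo - 1L) * (d + 2L)^2 + (cc - 1L) * (d + 2L) + rr
    acc <- rowsum(wt, idx)
    vec[as.integer(rownames(acc))] <- vec[as.integer(rownames(acc))] +
      acc[, 1L]
  }
  v <- as.vector(vec[2:(d + 1L), 2:(d + 1L), ])
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v[v > 0.2] <- 0.2
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Match descriptor sets with a ratio test
#'
#' Two-nearest-neighbour matching with the Lowe ratio criterion: a match
#' from A to B is kept only when its best Euclidean distance is below
#' `ratio` times the second-best. With fewer than two candidates in B the
#' match is dropped.
#'
#' @param desc_a,desc_b descriptor matrices (n x 128).
#' @param ratio Lowe ratio threshold in (0, 1].
#' @return Tibble with columns `idx_a`, `idx_b`, `distance`.
#' @export
match_descriptors <- function(desc_a, desc_b, ratio = 0.75) {
  empty <- tibble::tibble(idx_a = integer(), idx_b = integer(),
                          distance = numeric())
  if (nrow(desc_a) == 0L || nrow(desc_b) < 2L) return(empty)
  d2 <- outer(rowSums(desc_a^2), rowSums(desc_b^2), "+") -
    2 * tcrossprod(desc_a, desc_b)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  bi <- cbind(seq_len(nrow(d2)), best)
  d1 <- d2[bi]
  d2m <- d2
  d2m[bi] <- Inf
  second <- d2m[cbind(seq_len(nrow(d2)), max.col(-d2m, ties.method = "first"))]
  keep <- sqrt(d1) < ratio * sqrt(second)
  tibble::tibble(idx_a = which(keep), idx_b = best[keep],
                 distance = sqrt(d1[keep]))
}
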