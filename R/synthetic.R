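#' Synthetic sample with known ground truth
#'
#' Builds a complete `spat_sample` that emulates an imaging-based spatial
#' transcriptomics run, with every quantity recorded as ground truth:
#'
#' * cell centroids from uniform sampling with minimum-distance thinning;
#' * cell types assigned by vertical spatial bands whose widths follow
#'   `type_props`, so annotations have verifiable contents;
#' * near-circular cellular boundary polygons (jittered radius) with
#'   concentric nuclear boundaries;
#' * per-type expression profiles: one symmetric-Dirichlet base profile
#'   with each type's marker genes multiplied by `marker_fc`, then
#'   renormalized; optional extra fold change on `de_genes` (used for
#'   condition effects);
#' * per-cell library sizes ~ lognormal(log 200, 0.3), counts multinomial;
#' * one transcript point per count, Normal(centroid, sigma = 3 um)
#'   clipped to the cell disk, carrying the cell id;
#' * a nuclei image rendered as Gaussian blobs over a smooth background
#'   texture with Poisson noise (8-bit intensities);
#' * one annotation set labelling the type bands and one region set with a
#'   2 x 2 rectangle grid tiling the extent.
#'
#' All randomness comes from one seeded generator, so a fixed seed
#' reproduces the sample byte for byte.
#'
#' @param n_cells,n_genes,n_types,image_px,pixel_size,marker_fc,n_markers_per_type
#'   generation parameters (defaults are the package's standard study
#'   conditions).
#' @param seed integer seed.
#' @param type_props type proportions (band widths); default
#'   `c(0.5, 0.3, 0.2)` for three types, equal otherwise.
#' @param profiles optional pre-built n_types x n_genes profile matrix
#'   (rows sum to 1), e.g. shared across the samples of an experiment.
#' @param de_genes,de_fc optional indices of genes whose profile entries
#'   are multiplied by `de_fc` (then renormalized) in every type —
#'   a condition-level expression shift.
#' @param min_dist minimum distance between centroids, um.
#' @return List with `sample` (a `spat_sample`) and `truth` (a list of
#'   the planted quantities).
#' @export
generate_sample <- function(n_cells = 500L, n_genes = 100L, n_types = 3L,
                            image_px = 1024L, pixel_size = 0.5,
                            marker_fc = 4, n_markers_per_type = 10L,
                            seed = 0L, type_props = NULL, profiles = NULL,
                            de_genes = NULL, de_fc = 1, min_dist = 6) {
  stopifnot(n_cells >= 1L, n_genes >= 1L, n_types >= 1L,
            n_markers_per_type * n_types <= n_genes)
  withr::local_seed(seed)
  W <- image_px * pixel_size

  if (is.null(type_props)) {
    type_props <- if (n_types == 3L) c(0.5, 0.3, 0.2) else
      rep(1 / n_types, n_types)
  }
  stopifnot(length(type_props) == n_types)
  type_props <- type_props / sum(type_props)

  r_base <- min_dist / 2
  cents <- sample_centroids(n_cells, W, margin = r_base + 1, min_dist = min_dist)
  n_cells <- nrow(cents)
  ids <- sprintf("cell_%04d", seq_len(n_cells))
  band_edges <- cumsum(c(0, type_props)) * W
  type_idx <- findInterval(cents[, 1L], band_edges, rightmost.closed = TRUE)
  type_idx <- pmin(pmax(type_idx, 1L), n_types)
  type_names <- paste0("type_", seq_len(n_types))

  genes <- sprintf("gene_%03d", seq_len(n_genes))
  markers <- lapply(seq_len(n_types), function(t) {
    ((t - 1L) * n_markers_per_type + 1L):(t * n_markers_per_type)
  })
  if (is.null(profiles)) {
    profiles <- build_profiles(n_types, n_genes, markers, marker_fc)
  }
  if (!is.null(de_genes) && de_fc != 1) {
    profiles[, de_genes] <- profiles[, de_genes] * de_fc
    profiles <- profiles / rowSums(profiles)
  }

  lib <- pmax(1L, round(stats::rlnorm(n_cells, log(200), 0.3)))
  counts <- matrix(0, n_cells, n_genes, dimnames = list(ids, genes))
  for (i in seq_len(n_cells)) {
    counts[i, ] <- stats::rmultinom(1L, lib[i], profiles[type_idx[i], ])
  }

  radii <- r_base * (1 + stats::runif(n_cells, -0.15, 0.15))
  k <- 14L
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  boundaries <- dplyr::bind_rows(
    tibble::tibble(cell_id = ids, boundary_type = "cellular",
                   coords = lapply(seq_len(n_cells), function(i) {
                     cbind(cents[i, 1L] + radii[i] * cos(ang),
                           cents[i, 2L] + radii[i] * sin(ang))
                   })),
    tibble::tibble(cell_id = ids, boundary_type = "nuclear",
                   coords = lapply(seq_len(n_cells), function(i) {
                     cbind(cents[i, 1L] + 0.55 * radii[i] * cos(ang),
                           cents[i, 2L] + 0.55 * radii[i] * sin(ang))
                   })))

  # transcripts: one point per count, clipped inside the cell disk
  per_cell <- rowSums(counts)
  total <- sum(per_cell)
  tx_gene <- unlist(lapply(seq_len(n_cells), function(i) {
    rep(genes, counts[i, ])
  }), use.names = FALSE)
  tx_cell <- rep(ids, per_cell)
  dx <- stats::rnorm(total, 0, 3); dy <- stats::rnorm(total, 0, 3)
  rmax <- rep(radii, per_cell) * 0.9
  d <- sqrt(dx^2 + dy^2)
  shrink <- ifelse(d > rmax, rmax / d, 1)
  tx <- tibble::tibble(
    x = rep(cents[, 1L], per_cell) + dx * shrink,
    y = rep(cents[, 2L], per_cell) + dy * shrink,
    gene = tx_gene,
    quality = stats::runif(total, 20, 40),
    cell_id = tx_cell)

  img <- render_nuclei_image(cents / pixel_size, 0.55 * radii / pixel_size,
                             image_px)
  nuclei <- pixel_image(img, pixel_size, channel_names = "dapi",
                        name = "nuclei")

  cell_tbl <- tibble::tibble(cell_id = ids, centroid_x = cents[, 1L],
                             centroid_y = cents[, 2L],
                             cell_type = type_names[type_idx])
  layer <- cell_layer(counts, cell_tbl,
                      tibble::tibble(feature = genes), boundaries)

  bands <- polygon_set(
    paste0("band_", seq_len(n_types)), type_names,
    lapply(seq_len(n_types), function(t) {
      rect_ring(band_edges[t], 0, band_edges[t + 1L], W)
    }), scope = "annotation")
  grid <- polygon_set(
    c("core_1_1", "core_1_2", "core_2_1", "core_2_2"), "core",
    list(rect_ring(0, 0, W / 2, W / 2), rect_ring(W / 2, 0, W, W / 2),
         rect_ring(0, W / 2, W / 2, W), rect_ring(W / 2, W / 2, W, W)),
    scope = "region")

  s <- spat_sample(uid = mint_uid(), metadata = list(source = "synthetic"),
                   images = list(nuclei = nuclei), transcripts = tx,
                   cells = list(default = layer),
                   annotations = list(bands = bands),
                   regions = list(grid = grid))
  truth <- list(centroids = cell_tbl, type_props = type_props,
                band_edges = band_edges, profiles = profiles,
                markers = markers, marker_fc = marker_fc,
                lib_sizes = lib, genes = genes, seed = seed,
                de_genes = de_genes, de_fc = de_fc)
  list(sample = s, truth = truth)
}

build_profiles <- function(n_types, n_genes, markers, marker_fc) {
  base <- stats::rgamma(n_genes, 1)
  base <- base / sum(base)
  profiles <- matrix(rep(base, each = n_types), n_types, n_genes)
  for (t in seq_len(n_types)) {
    profiles[t, markers[[t]]] <- profiles[t, markers[[t]]] * marker_fc
  }
  profiles / rowSums(profiles)
}

# Uniform centroids in [margin, W - margin]^2 thinned to a minimum
# distance; sequential rejection with a retry budget.
sample_centroids <- function(n, W, margin, min_dist) {
  lo <- margin; hi <- W - margin
  stopifnot(hi > lo)
  xs <- numeric(n); ys <- numeric(n)
  got <- 0L
  tries <- 0L; max_tries <- 200L * n
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    x <- stats::runif(1L, lo, hi); y <- stats::runif(1L, lo, hi)
    if (got == 0L ||
        min((xs[seq_len(got)] - x)^2 + (ys[seq_len(got)] - y)^2) >=
          min_dist^2) {
      got <- got + 1L
      xs[got] <- x; ys[got] <- y
    }
  }
  if (got < n) {
    stop(sprintf("infeasible packing: placed %d of %d centroids", got, n),
         call. = FALSE)
  }
  cbind(xs, ys)
}

# Gaussian nuclear blobs + smooth background texture + Poisson noise,
# 8-bit integer intensities. Centres/radii in pixels.
render_nuclei_image <- function(centers_px, sigmas_px, image_px) {
  canvas <- matrix(0, image_px, image_px)
  amps <- stats::runif(nrow(centers_px), 120, 220)
  for (i in seq_len(nrow(centers_px))) {
    cx <- centers_px[i, 1L]; cy <- centers_px[i, 2L]
    sg <- max(sigmas_px[i], 1)
    rad <- ceiling(3 * sg)
    c0 <- max(1L, floor(cx - rad)); c1 <- min(image_px, ceiling(cx + rad))
    r0 <- max(1L, floor(cy - rad)); r1 <- min(image_px, ceiling(cy + rad))
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-(((c0:c1) - 0.5 - cx)^2) / (2 * sg^2))
    gy <- exp(-(((r0:r1) - 0.5 - cy)^2) / (2 * sg^2))
    canvas[r0:r1, c0:c1] <- canvas[r0:r1, c0:c1] + amps[i] * outer(gy, gx)
  }
  # smooth autofluorescence-like background
  coarse <- matrix(stats::runif(32L * 32L), 32L, 32L)
  bg <- EBImage::resize(coarse, w = image_px, h = image_px)
  bg <- EBImage::gblur(bg, sigma = 8)
  bg <- 25 * (bg - min(bg)) / max(1e-12, diff(range(bg)))
  lambda <- pmin(canvas + bg + 3, 250)
  img <- matrix(stats::rpois(length(lambda), lambda), image_px, image_px)
  pmin(img, 255)
}

#' Synthetic registration pair with a planted transform
#'
#' Renders a nuclei image (fixed), plants a similarity transform —
#' rotation about the image centre, isotropic scale, pixel shift — and
#' produces the moving image by resampling the fixed image through the
#' planted transform, then perturbing it mildly (gamma 1.1, Gaussian
#' noise sd 2/255).
#'
#' @param seed integer seed.
#' @param rotation_deg rotation in degrees (|rotation| <= 45).
#' @param scale isotropic scale in \[0.5, 2\].
#' @param shift_px length-2 pixel shift.
#' @param image_px image edge length.
#' @param n_cells number of rendered nuclei.
#' @return List with `fixed`, `moving` (`pixel_image`s) and `transform`
#'   (the planted 3 x 3 matrix mapping moving to fixed pixels).
#' @export
generate_registration_pair <- function(seed = 0L, rotation_deg = 10,
                                       scale = 1.1, shift_px = c(30, -20),
                                       image_px = 1024L, n_cells = 400L) {
  stopifnot(abs(rotation_deg) <= 45, scale >= 0.5, scale <= 2)
  withr::local_seed(seed)
  W <- image_px  # pixel units; pixel_size 0.5 um/px for the container
  cents <- sample_centroids(n_cells, W, margin = 6, min_dist = 10)
  radii <- stats::runif(n_cells, 2, 3.5)
  img <- render_nuclei_image(cents, radii, image_px)
  fixed <- pixel_image(img, 0.5, channel_names = "dapi", name = "nuclei")

  th <- rotation_deg * pi / 180
  ctr <- (image_px - 1) / 2
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) * scale
  tr <- c(ctr, ctr) - R %*% c(ctr, ctr) + shift_px
  planted <- rbind(cbind(R, tr), c(0, 0, 1))

  mov <- img_pixels(apply_transform_image(fixed, solve(planted),
                                          c(image_px, image_px)))
  mov <- 255 * (pmax(mov, 0) / 255)^1.1
  mov <- mov + stats::rnorm(length(mov), 0, 2)
  mov <- round(pmin(pmax(mov, 0), 255))
  moving <- pixel_image(matrix(mov, image_px, image_px), 0.5,
                        channel_names = "he", name = "histology")
  list(fixed = fixed, moving = moving, transform = planted)
}

#' Synthetic multi-sample experiment with planted condition effects
#'
#' Independent synthetic samples sharing one base expression profile,
#' alternately assigned to conditions. Treated samples get (i) a
#' composition shift — +0.15 to the type-1 fraction, the remainder
#' rescaled proportionally — and (ii) a planted differential-expression
#' gene set (the last `n_de` genes multiplied by `de_fc` in every type).
#' Metadata carries uid, condition and donor.
#'
#' @param n_samples number of samples (>= 1).
#' @param conditions condition labels, assigned round-robin.
#' @param seed integer seed.
#' @param n_cells,n_genes,image_px per-sample generation size; samples are
#'   TMA-core sized by default.
#' @param n_de,de_fc planted differential-expression gene count and fold
#'   change.
#' @return List with `experiment` (a `spat_experiment`) and `truth`.
#' @export
generate_experiment <- function(n_samples = 5L,
                                conditions = c("treated", "control"),
                                seed = 0L, n_cells = 500L, n_genes = 100L,
                                image_px = 512L, n_de = 10L, de_fc = 4) {
  stopifnot(n_samples >= 1L)
  withr::local_seed(seed)
  base_props <- c(0.5, 0.3, 0.2)
  treated_props <- c(base_props[1L] + 0.15,
                     base_props[-1L] * (1 - base_props[1L] - 0.15) /
                       sum(base_props[-1L]))
  markers <- lapply(1:3, function(t) ((t - 1L) * 10L + 1L):(t * 10L))
  profiles <- build_profiles(3L, n_genes, markers, marker_fc = 4)
  de_genes <- (n_genes - n_de + 1L):n_genes
  cond <- conditions[((seq_len(n_samples) - 1L) %% length(conditions)) + 1L]
  sample_seeds <- sample.int(1e6L, n_samples)

  exp <- spat_experiment()
  truths <- list()
  for (i in seq_len(n_samples)) {
    treated <- cond[i] == conditions[1L]
    g <- generate_sample(
      n_cells = n_cells, n_genes = n_genes, image_px = image_px,
      seed = sample_seeds[i],
      type_props = if (treated) treated_props else base_props,
      profiles = profiles,
      de_genes = if (treated) de_genes else NULL,
      de_fc = if (treated) de_fc else 1)
    exp <- add_sample(exp, g$sample,
                      list(condition = cond[i], donor = paste0("donor_", i)))
    truths[[sample_uid(g$sample)]] <- g$truth
  }
  truth <- list(conditions = cond, base_props = base_props,
                treated_props = treated_props, de_genes = de_genes,
                de_fc = de_fc, profiles = profiles,
                treated_uids = exp$metadata$uid[cond == conditions[1L]],
                n_treated = sum(cond == conditions[1L]),
                samples = truths)
  list(experiment = exp, truth = truth)
}

#' Synthetic count matrices for two groups with optional planted markers
#'
#' Draws two groups of cells from one symmetric-Dirichlet profile;
#' group A's profile has `lfc_genes` multiplied by `fc` (then
#' renormalized). Library sizes are lognormal(log 200, 0.3), counts
#' multinomial — the null (`fc = 1`) gives identically distributed
#' groups for type-I-error calibration.
#'
#' @param n_a,n_b cells per group.
#' @param n_genes number of genes.
#' @param lfc_genes indices of planted genes (group A), or NULL.
#' @param fc planted fold change.
#' @param seed integer seed.
#' @return List with count matrices `a` and `b` (cells x genes).
#' @export
generate_count_groups <- function(n_a = 200L, n_b = 200L, n_genes = 100L,
                                  lfc_genes = NULL, fc = 1, seed = 0L) {
  withr::local_seed(seed)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  base <- stats::rgamma(n_genes, 1)
  base <- base / sum(base)
  prof_a <- base
  if (!is.null(lfc_genes) && fc != 1) {
    prof_a[lfc_genes] <- prof_a[lfc_genes] * fc
    prof_a <- prof_a / sum(prof_a)
  }
  draw <- function(n, prof) {
    lib <- pmax(1L, round(stats::rlnorm(n, log(200), 0.3)))
    m <- t(vapply(seq_len(n), function(i) {
      stats::rmultinom(1L, lib[i], prof)[, 1L]
    }, numeric(n_genes)))
    dimnames(m) <- list(sprintf("c%04d", seq_len(n)), genes)
    m
  }
  list(a = draw(n_a, prof_a), b = draw(n_b, base))
}
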