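test_that("generation is deterministic under a fixed seed", {
  a <- generate_sample(n_cells = 50, image_px = 128, seed = 21)
  b <- generate_sample(n_cells = 50, image_px = 128, seed = 21)
  a$sample$uid <- b$sample$uid <- "fixed"
  expect_identical(digest::digest(img_pixels(a$sample$images$nuclei)),
                   digest::digest(img_pixels(b$sample$images$nuclei)))
  expect_identical(digest::digest(sample_transcripts(a$sample)),
                   digest::digest(sample_transcripts(b$sample)))
  expect_identical(digest::digest(as.matrix(a$sample$cells$default$matrix)),
                   digest::digest(as.matrix(b$sample$cells$default$matrix)))
  c_ <- generate_sample(n_cells = 50, image_px = 128, seed = 22)
  expect_false(identical(digest::digest(img_pixels(a$sample$images$nuclei)),
                         digest::digest(img_pixels(c_$sample$images$nuclei))))
})

test_that("counts, library sizes and transcripts obey construction identities", {
  g <- small_sample()
  expect_identical(sum(g$sample$cells$default$matrix),
                   sum(g$truth$lib_sizes))
  expect_identical(nrow(sample_transcripts(g$sample)),
                   as.integer(sum(g$sample$cells$default$matrix)))
  # every transcript carries the id of the cell that emitted it
  tx <- sample_transcripts(g$sample)
  per_cell <- table(tx$cell_id)
  m <- g$sample$cells$default$matrix
  expect_identical(as.integer(per_cell[rownames(m)]),
                   as.integer(Matrix::rowSums(m)))
})

test_that("marker genes are elevated by about the planted fold change", {
  g <- generate_sample(n_cells = 600, image_px = 512, seed = 21)
  m <- as.matrix(g$sample$cells$default$matrix)
  types <- g$sample$cells$default$cell_table$cell_type
  # mean marker expression in the owning type vs the other types
  for (t in 1:3) {
    mk <- g$truth$markers[[t]]
    own <- colMeans(m[types == paste0("type_", t), mk, drop = FALSE])
    oth <- colMeans(m[types != paste0("type_", t), mk, drop = FALSE])
    ratio <- sum(own) / sum(oth)
    expect_lt(abs(ratio - g$truth$marker_fc) / g$truth$marker_fc, 0.25)
  }
})

test_that("cell types follow the planted spatial bands", {
  g <- small_sample()
  ct <- g$sample$cells$default$cell_table
  band <- findInterval(ct$centroid_x, g$truth$band_edges,
                       rightmost.closed = TRUE)
  expect_identical(paste0("type_", band), ct$cell_type)
  # annotations cover the bands, regions tile the extent
  expect_identical(nrow(g$sample$annotations$bands), 3L)
  expect_identical(nrow(g$sample$regions$grid), 4L)
  ex <- get_extent(g$sample)
  grid_area <- sum(vapply(g$sample$regions$grid$coords, polygon_area, 0))
  expect_equal(grid_area, unname((ex["xmax"] - ex["xmin"]) *
                                   (ex["ymax"] - ex["ymin"])))
})

test_that("experiments plant conditions, composition shifts and DE genes", {
  ge <- generate_experiment(n_samples = 5, seed = 7, n_cells = 120,
                            image_px = 256)
  e <- ge$experiment
  md <- experiment_metadata(e)
  expect_identical(nrow(md), 5L)
  expect_setequal(unique(md$condition), c("treated", "control"))
  expect_identical(sum(md$condition == "treated"), ge$truth$n_treated)
  expect_identical(n_samples(query(e, condition == "treated")),
                   ge$truth$n_treated)
  # determinism
  ge2 <- generate_experiment(n_samples = 5, seed = 7, n_cells = 120,
                             image_px = 256)
  expect_identical(
    digest::digest(as.matrix(e$samples[[1]]$cells$default$matrix)),
    digest::digest(as.matrix(ge2$experiment$samples[[1]]$cells$default$matrix)))
  # planted treated composition favours type_1 by construction
  expect_gt(ge$truth$treated_props[1], ge$truth$base_props[1])
  expect_equal(sum(ge$truth$treated_props), 1)
})

test_that("registration pairs are reproducible and seed-distinct", {
  a <- generate_registration_pair(seed = 5, image_px = 128, n_cells = 40)
  b <- generate_registration_pair(seed = 5, image_px = 128, n_cells = 40)
  expect_identical(digest::digest(img_pixels(a$fixed)),
                   digest::digest(img_pixels(b$fixed)))
  expect_identical(a$transform, b$transform)
  c_ <- generate_registration_pair(seed = 6, image_px = 128, n_cells = 40)
  expect_false(identical(digest::digest(img_pixels(a$fixed)),
                         digest::digest(img_pixels(c_$fixed))))
  # identity parameters give a noisy copy of the fixed image
  id <- generate_registration_pair(seed = 5, rotation_deg = 0, scale = 1,
                                   shift_px = c(0, 0), image_px = 128,
                                   n_cells = 40)
  expect_equal(id$transform, diag(3), tolerance = 1e-12)
  diff <- abs(img_pixels(id$moving) - img_pixels(id$fixed))
  expect_lt(mean(diff), 8)  # gamma + noise only
})

test_that("infeasible packing raises an error instead of looping forever", {
  expect_error(generate_sample(n_cells = 500, image_px = 32, seed = 1),
               "infeasible packing")
})
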