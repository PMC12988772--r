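test_that("extent prefers the primary image, falls back to centroids", {
  img <- pixel_image(matrix(0, 100, 200), 0.5)
  s <- spat_sample(images = list(im = img))
  expect_equal(unname(get_extent(s)), c(0, 0, 100, 50))

  ct <- tibble::tibble(cell_id = c("a", "b"), centroid_x = c(1, 5),
                       centroid_y = c(2, 9))
  l <- cell_layer(matrix(1, 2, 1), ct)
  s2 <- spat_sample(cells = list(default = l))
  expect_equal(unname(get_extent(s2)), c(1, 2, 5, 9))

  expect_error(get_extent(spat_sample()), "no extent")
})

test_that("extent of a synthetic sample bounds every coordinate category", {
  s <- small_sample()$sample
  ex <- get_extent(s)
  tx <- sample_transcripts(s)
  ct <- s$cells$default$cell_table
  coords <- rbind(cbind(tx$x, tx$y), cbind(ct$centroid_x, ct$centroid_y),
                  do.call(rbind, s$annotations$bands$coords),
                  do.call(rbind, s$regions$grid$coords))
  expect_true(all(coords[, 1] >= ex["xmin"] - 1e-9 &
                    coords[, 1] <= ex["xmax"] + 1e-9))
  expect_true(all(coords[, 2] >= ex["ymin"] - 1e-9 &
                    coords[, 2] <= ex["ymax"] + 1e-9))
})

test_that("identity crop preserves all record counts", {
  s <- small_sample()$sample
  ex <- get_extent(s)
  full <- rect4(ex["xmin"], ex["ymin"], ex["xmax"], ex["ymax"])
  cr <- crop_sample(s, full, shift_origin = FALSE)
  expect_identical(sample_summary(cr)$n, sample_summary(s)$n)
})

test_that("crop keeps exactly the cells and transcripts inside the polygon", {
  s <- small_sample()$sample
  set.seed(9)
  poly <- rect4(runif(1, 0, 60), runif(1, 0, 60),
                runif(1, 70, 128), runif(1, 70, 128))
  cr <- crop_sample(s, poly)
  ct <- s$cells$default$cell_table
  keep <- points_in_polygon(cbind(ct$centroid_x, ct$centroid_y), poly)
  expect_setequal(cr$cells$default$cell_table$cell_id, ct$cell_id[keep])
  tx <- sample_transcripts(s)
  expect_identical(nrow(sample_transcripts(cr)),
                   sum(points_in_polygon(cbind(tx$x, tx$y), poly)))
  # matrix rows follow their cells
  expect_identical(rownames(cr$cells$default$matrix),
                   cr$cells$default$cell_table$cell_id)
  # boundaries follow too (both nuclear and cellular per kept cell)
  expect_true(all(cr$cells$default$boundaries$cell_id %in% ct$cell_id[keep]))
})

test_that("crop is idempotent over the first crop's extent", {
  s <- small_sample()$sample
  poly <- rect4(10, 10, 90, 100)
  cr1 <- crop_sample(s, poly)
  ex <- get_extent(cr1)
  # second crop over the full extent of the first changes nothing
  cr2 <- crop_sample(cr1, rect4(ex["xmin"], ex["ymin"],
                                ex["xmax"], ex["ymax"]))
  expect_identical(sample_summary(cr2)$n, sample_summary(cr1)$n)
})

test_that("disjoint covering polygons partition the cells", {
  s <- small_sample()$sample
  W <- unname(get_extent(s)["xmax"])
  parts <- list(rect4(0, 0, W / 2, W / 2), rect4(W / 2, 0, W, W / 2),
                rect4(0, W / 2, W / 2, W), rect4(W / 2, W / 2, W, W))
  counts <- vapply(parts, function(p) {
    n_cells(crop_sample(s, p)$cells$default)
  }, 0L)
  expect_identical(sum(counts), n_cells(s$cells$default))
})

test_that("a non-intersecting crop returns an empty sample with a warning", {
  s <- toy_sample()
  w <- testthat::capture_warnings(
    cr <- crop_sample(s, rect4(100, 100, 110, 110)))
  expect_match(w, "retained no cells|does not intersect", all = FALSE)
  expect_identical(n_cells(cr$cells$default), 0L)
  expect_identical(nrow(sample_transcripts(cr)), 0L)
  # all six categories still present
  expect_identical(sample_summary(cr)$category,
                   c("images", "transcripts", "cells", "units",
                     "annotations", "regions"))
})

test_that("shift_origin translates coordinates and records the offset", {
  s <- toy_sample()
  cr <- crop_sample(s, rect4(4, 4, 10, 10), shift_origin = TRUE)
  off <- cr$metadata$crop_offset
  expect_equal(unname(off), c(4, 4))
  parent <- s$cells$default$cell_table
  child <- cr$cells$default$cell_table
  for (id in child$cell_id) {
    i <- match(id, parent$cell_id)
    j <- match(id, child$cell_id)
    expect_equal(child$centroid_x[j], parent$centroid_x[i] - off["x"],
                 ignore_attr = TRUE)
  }
})

test_that("cell layers enforce cardinality and key invariants", {
  ct <- tibble::tibble(cell_id = c("a", "b"), centroid_x = 1:2,
                       centroid_y = 1:2)
  expect_error(cell_layer(matrix(1, 3, 2), ct), "row count")
  expect_error(cell_layer(matrix(1, 2, 2), ct,
                          tibble::tibble(feature = "g1")), "column count")
  expect_error(cell_layer(matrix(-1, 2, 2), ct), "non-negative")
  ct$cell_id <- c("a", "a")
  expect_error(cell_layer(matrix(1, 2, 2), ct), "unique")
  b <- tibble::tibble(cell_id = "zz", boundary_type = "cellular",
                      coords = list(unit_square()))
  ct$cell_id <- c("a", "b")
  expect_error(cell_layer(matrix(1, 2, 2), ct, boundaries = b),
               "keyed by known cell_ids")
})
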