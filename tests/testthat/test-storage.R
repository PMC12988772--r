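test_that("saveas then load reproduces every category exactly", {
  g <- small_sample()
  s <- g$sample
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  saveas_project(s, p)
  s2 <- load_sample(p)
  expect_identical(sample_uid(s2), sample_uid(s))
  expect_identical(sample_summary(s2)$n, sample_summary(s)$n)
  expect_true(all(s2$cells$default$matrix == s$cells$default$matrix))
  expect_identical(sum(s2$cells$default$matrix), sum(s$cells$default$matrix))
  tx <- sample_transcripts(s); tx2 <- sample_transcripts(s2)
  expect_lt(max(abs(tx$x - tx2$x)), 1e-6)
  expect_lt(max(abs(tx$y - tx2$y)), 1e-6)
  expect_identical(tx2$gene, tx$gene)
  expect_identical(tx2$cell_id, tx$cell_id)
  expect_identical(img_pixels(s2$images$nuclei), img_pixels(s$images$nuclei))
  # polygon vertex counts survive
  expect_identical(vapply(s2$annotations$bands$coords, nrow, 0L),
                   vapply(s$annotations$bands$coords, nrow, 0L))
  expect_identical(s2$metadata$source, s$metadata$source)
})

test_that("an empty sample round-trips with six empty categories", {
  s <- spat_sample(uid = "empty01")
  root <- withr::local_tempdir()
  saveas_project(s, file.path(root, "e"))
  s2 <- load_sample(file.path(root, "e"))
  expect_identical(sample_summary(s2)$n, rep(0L, 6L))
})

test_that("saveas refuses a non-empty target without overwrite", {
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  dir.create(p)
  writeLines("x", file.path(p, "junk.txt"))
  expect_error(saveas_project(toy_sample(), p), "not empty")
  expect_silent(saveas_project(toy_sample(), p, overwrite = TRUE))
})

test_that("save rewrites only variable data; static digests are stable", {
  s <- toy_sample()
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  saveas_project(s, p)
  static_files <- list.files(file.path(p, "static"), recursive = TRUE,
                             full.names = TRUE)
  pre <- vapply(static_files, digest::digest, "", algo = "sha256",
                file = TRUE)
  ann_file <- file.path(p, "variable", "annotations", "roi.geojson")
  pre_ann <- digest::digest(ann_file, algo = "sha256", file = TRUE)
  s$annotations$roi$class_label[1] <- "stroma"
  save_project(s, p)
  post <- vapply(static_files, digest::digest, "", algo = "sha256",
                 file = TRUE)
  expect_identical(post, pre)
  expect_false(identical(digest::digest(ann_file, algo = "sha256",
                                        file = TRUE), pre_ann))
  expect_identical(load_sample(p)$annotations$roi$class_label[1], "stroma")
})

test_that("save validates the project UID", {
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  saveas_project(toy_sample(), p)
  other <- toy_sample()
  expect_error(save_project(other, p), "wrong project")
})

test_that("images and transcripts load lazily, payload read on access", {
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  saveas_project(small_sample()$sample, p)
  imgs <- load_modality(p, "images")
  expect_identical(img_read_count(imgs$nuclei), 0L)
  expect_identical(img_shape(imgs$nuclei)[1:2], c(256L, 256L))
  expect_identical(img_read_count(imgs$nuclei), 0L)  # shape is metadata
  invisible(img_pixels(imgs$nuclei))
  expect_identical(img_read_count(imgs$nuclei), 1L)
  s2 <- load_sample(p)
  expect_identical(spatmosaic:::table_read_count(s2$transcripts), 0L)
  invisible(sample_transcripts(s2))
  expect_identical(spatmosaic:::table_read_count(s2$transcripts), 1L)
})

test_that("static corruption is detected at first payload access", {
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  saveas_project(toy_sample(), p)
  tif <- file.path(p, "static", "images", "nuclei.tif")
  bytes <- readBin(tif, "raw", file.info(tif)$size)
  bytes[length(bytes)] <- as.raw(bitwXor(as.integer(bytes[length(bytes)]),
                                         255L))
  writeBin(bytes, tif)
  s2 <- load_sample(p)  # opening is fine: lazy
  expect_error(img_pixels(s2$images$nuclei), "corruption")
})

test_that("load_modality returns single layers and rejects unknown keys", {
  root <- withr::local_tempdir()
  p <- file.path(root, "proj")
  saveas_project(small_sample()$sample, p)
  l <- load_modality(p, "cells", "default")
  expect_s3_class(l, "cell_layer")
  expect_identical(dim(l$matrix), dim(small_sample()$sample$cells$default$matrix))
  expect_error(load_modality(p, "cells", "other"), "unknown layer")
  expect_error(load_modality(p, "tables"), "unknown category")
})

test_that("experiments save and load with metadata in order", {
  e <- spat_experiment()
  e <- add_sample(e, toy_sample(), list(condition = "a"))
  e <- add_sample(e, toy_sample(), list(condition = "b"))
  root <- withr::local_tempdir()
  p <- file.path(root, "exp")
  saveas_project(e, p)
  e2 <- load_experiment(p)
  expect_identical(experiment_metadata(e2)$uid, experiment_metadata(e)$uid)
  expect_identical(experiment_metadata(e2)$condition, c("a", "b"))
  expect_identical(n_samples(e2), 2L)
})
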