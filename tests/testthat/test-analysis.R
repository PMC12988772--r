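test_that("composition rows are proportions that sum to one", {
  e <- add_sample(spat_experiment(), toy_sample(), list(condition = "x"))
  comp <- cell_composition(e, group_key = "uid")
  expect_equal(unname(unlist(comp[1, c("A", "B")])), c(2 / 3, 1 / 3))
  expect_equal(sum(comp[1, -1]), 1)
  # two identical samples grouped together give the same row
  e2 <- add_sample(e, toy_sample(), list(condition = "x"))
  comp2 <- cell_composition(e2, group_key = "condition")
  expect_equal(unname(unlist(comp2[1, c("A", "B")])), c(2 / 3, 1 / 3))
  expect_error(cell_composition(e, group_key = "nope"), "unknown metadata")
  expect_error(cell_composition(e, celltype_key = "nope"), "missing")
})

test_that("composition is invariant under cell order permutation", {
  g <- small_sample()
  e <- add_sample(spat_experiment(), g$sample, list(condition = "x"))
  comp <- cell_composition(e)
  l <- g$sample$cells$default
  set.seed(2)
  perm <- sample(n_cells(l))
  s2 <- g$sample
  s2$uid <- sample_uid(g$sample)
  s2$cells$default <- cell_layer(l$matrix[perm, ], l$cell_table[perm, ],
                                 l$feature_table, l$boundaries)
  e2 <- spat_experiment(list(s2), experiment_metadata(e))
  expect_equal(as.data.frame(cell_composition(e2)), as.data.frame(comp))
})

test_that("cell-type density is counts per polygon area in mm^2", {
  ct <- tibble::tibble(cell_id = as.character(1:12),
                       centroid_x = c(runif(10, 0, 1000), 1500, 1600),
                       centroid_y = c(runif(10, 0, 1000), 500, 500),
                       cell_type = c(rep("A", 10), "B", "B"))
  l <- cell_layer(matrix(1, 12, 1), ct)
  s <- spat_sample(cells = list(default = l),
                   regions = list(rois = polygon_set(
                     "sq", "roi", list(rect4(0, 0, 1000, 1000)),
                     scope = "region")))
  d <- cell_type_density(s, "rois")
  expect_equal(d$density_per_mm2[d$cell_type == "A"], 10)
  expect_equal(d$density_per_mm2[d$cell_type == "B"], 0)
  # doubling counts within the polygon doubles density
  ct2 <- dplyr::bind_rows(ct, dplyr::mutate(ct, cell_id = paste0("d", cell_id)))
  s$cells$default <- cell_layer(matrix(1, 24, 1), ct2)
  d2 <- cell_type_density(s, "rois")
  expect_equal(d2$density_per_mm2[d2$cell_type == "A"], 20)
  # zero-area polygon is an error
  s$regions$bad <- polygon_set("ln", "roi",
                               list(cbind(c(0, 1, 2), c(0, 0.5, 1) * 0)),
                               scope = "region")
  expect_error(cell_type_density(s, "bad"), "zero area")
})

test_that("density matches a brute-force count/area oracle on random polygons", {
  g <- small_sample()
  s <- g$sample
  set.seed(12)
  polys <- lapply(1:3, function(i) {
    ang <- sort(runif(7, 0, 2 * pi))
    r <- runif(7, 20, 60)
    cbind(64 + r * cos(ang), 64 + r * sin(ang))
  })
  s$annotations$probe <- polygon_set(paste0("p", 1:3), "probe", polys)
  d <- cell_type_density(s, "probe")
  ct <- s$cells$default$cell_table
  for (i in 1:3) {
    inside <- points_in_polygon(cbind(ct$centroid_x, ct$centroid_y),
                                polys[[i]])
    for (tp in unique(ct$cell_type)) {
      expected <- sum(inside & ct$cell_type == tp) /
        (polygon_area(polys[[i]]) / 1e6)
      expect_equal(
        d$density_per_mm2[d$polygon == paste0("p", i) & d$cell_type == tp],
        expected)
    }
  }
})

test_that("BH adjustment reproduces hand-computed worked examples", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # step-up recurrence: q_(i) = min(q_(i+1), p_(i) * n / i)
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  qs <- p[o] * 50 / seq_len(50)
  for (i in 49:1) qs[i] <- min(qs[i], qs[i + 1])
  expect_equal(q[o], qs)
  expect_lte(max(q), 1)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("identical groups give zero fold change and flat p-values", {
  g <- generate_count_groups(30, 30, 40, seed = 2)
  d <- differential_expression(g$a, g$a)
  expect_true(all(d$lfc == 0))
  expect_true(all(d$p_value > 0.99))
})

test_that("swapping the groups negates the fold change, p unchanged", {
  g <- generate_count_groups(50, 60, 40, seed = 4)
  d1 <- differential_expression(g$a, g$b)
  d2 <- differential_expression(g$b, g$a)
  expect_equal(d1$lfc, -d2$lfc)
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$statistic, -d2$statistic)
})

test_that("the rank-sum backend agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:5) {
    a <- rpois(40, sample(2:6, 1)) * runif(40, 0.5, 2)
    b <- rpois(55, sample(2:6, 1)) * runif(55, 0.5, 2)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_equal(spatmosaic:::rank_sum_z(a, b)[2], ref, tolerance = 1e-12)
  }
})

test_that("differential expression validates inputs and intersects features", {
  g <- generate_count_groups(10, 10, 20, seed = 5)
  expect_error(differential_expression(g$a[1, , drop = FALSE], g$b),
               "at least 2")
  b2 <- g$b
  colnames(b2) <- paste0("other_", seq_len(ncol(b2)))
  expect_error(differential_expression(g$a, b2), "feature mismatch")
  b3 <- g$b[, 1:15]
  expect_warning(d <- differential_expression(g$a, b3), "shared features")
  expect_identical(nrow(d), 15L)
})

test_that("pseudobulk sums match brute-force per-cell summation", {
  ge <- generate_experiment(n_samples = 4, seed = 2, n_cells = 80,
                            image_px = 192)
  e <- ge$experiment
  pb <- pseudobulk(e, group_key = "condition")
  # brute force: sum raw counts cell by cell per condition
  md <- experiment_metadata(e)
  for (cond in unique(md$condition)) {
    tot <- NULL
    for (i in which(md$condition == cond)) {
      m <- e$samples[[i]]$cells$default$matrix
      cs <- Matrix::colSums(m)
      tot <- if (is.null(tot)) cs else tot + cs
    }
    got <- pb[pb$group == cond, ]
    expect_equal(got$count[match(names(tot), got$feature)],
                 unname(tot))
  }
  # conservation across groups
  grand <- sum(vapply(e$samples, function(s) sum(s$cells$default$matrix), 0))
  expect_equal(sum(pb$count), grand)
  # single sample, single group equals its column sums
  e1 <- spat_experiment(e$samples[1], md[1, ])
  pb1 <- pseudobulk(e1, group_key = "uid")
  cs <- Matrix::colSums(e$samples[[1]]$cells$default$matrix)
  expect_equal(pb1$count[match(names(cs), pb1$feature)], unname(cs))
})

test_that("tidy, glance and autoplot work on analysis results", {
  g <- generate_count_groups(40, 40, 30, lfc_genes = 1:5, fc = 4, seed = 6)
  d <- differential_expression(g$a, g$b)
  expect_s3_class(tidy(d), "tbl_df")
  gl <- glance(d)
  expect_identical(gl$n_features, 30L)
  expect_s3_class(autoplot(d), "ggplot")
  e <- add_sample(spat_experiment(), toy_sample(), list(condition = "x"))
  expect_s3_class(autoplot(cell_composition(e)), "ggplot")
  expect_s3_class(plot_cell_map(toy_sample()), "ggplot")
})
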