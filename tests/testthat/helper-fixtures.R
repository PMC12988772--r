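# Shared fixtures, built in code. The generated small sample is cached per
# session since several files only read from it.

unit_square <- function() cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

rect4 <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

small_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_sample(n_cells = 120L, image_px = 256L, seed = 1L)
    }
    cache
  }
})

# A hand-built 3-cell layer on a 10x10 um frame for exact checks.
toy_layer <- function() {
  m <- rbind(c(2, 0, 1), c(0, 3, 0), c(1, 1, 4))
  colnames(m) <- c("g1", "g2", "g3")
  ct <- tibble::tibble(cell_id = c("a", "b", "c"),
                       centroid_x = c(2, 5, 8), centroid_y = c(2, 5, 8),
                       cell_type = c("A", "A", "B"))
  sq <- function(cx, cy, r = 1.2) {
    cbind(cx + c(-r, r, r, -r), cy + c(-r, -r, r, r))
  }
  b <- tibble::tibble(
    cell_id = rep(c("a", "b", "c"), 2L),
    boundary_type = rep(c("cellular", "nuclear"), each = 3L),
    coords = list(sq(2, 2), sq(5, 5), sq(8, 8),
                  sq(2, 2, 0.6), sq(5, 5, 0.6), sq(8, 8, 0.6)))
  cell_layer(m, ct, boundaries = b)
}

toy_sample <- function(uid = NULL) {
  img <- pixel_image(matrix(seq_len(400) %% 7, 20, 20), 0.5,
                     channel_names = "dapi", name = "nuclei")
  tx <- tibble::tibble(x = c(1, 4, 9), y = c(1, 6, 9),
                       gene = c("g1", "g2", "g3"))
  ann <- polygon_set("tumor_1", "tumor", list(rect4(1, 1, 6, 6)),
                     scope = "annotation")
  reg <- polygon_set(c("left", "right"), "core",
                     list(rect4(0, 0, 5, 10), rect4(5, 0, 10, 10)),
                     scope = "region")
  spat_sample(uid = uid, images = list(nuclei = img), transcripts = tx,
              cells = list(default = toy_layer()),
              annotations = list(roi = ann), regions = list(halves = reg))
}
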