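#' Flat keyed export of a sample
#'
#' Flattens the sample hierarchy into a directory of keyed element groups
#' — `images`, `points`, `shapes` and `tables` — the way flat,
#' keyword-addressed spatial frameworks organize data. Keys follow
#' `<category>/<layer>`; an `elements.json` index maps each key to its
#' files, and [from_flat()] restores the hierarchy losslessly for
#' directories produced here.
#'
#' One image yields one `images` element; transcripts one `points`
#' element; each cell layer one `tables` element plus one `shapes` element
#' holding its boundary rings (nuclear and cellular distinguished by a
#' property); each unit layer a `tables` + `shapes` pair; each
#' annotation/region set one `shapes` element.
#'
#' @param sample a `spat_sample`.
#' @param path target directory (created, must not exist).
#' @return Invisibly, the element index (named list).
#' @export
to_flat <- function(sample, path) {
  if (dir.exists(path) && length(list.files(path)) > 0L) {
    stop(sprintf("target '%s' is not empty", path), call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  elements <- list()
  add <- function(key, type, files) {
    if (key %in% names(elements)) {
      stop(sprintf("naming error: duplicate element key '%s'", key),
           call. = FALSE)
    }
    elements[[key]] <<- list(type = type, files = files)
  }
  flat_name <- function(key) gsub("/", "__", fs_safe_key(key))

  for (nm in names(sample$images)) {
    key <- paste0("images/", nm)
    f <- paste0(flat_name(key), ".tif")
    write_image_tiff(sample$images[[nm]], file.path(path, f))
    add(key, "image", c(f, paste0(f, ".json")))
  }
  if (!is.null(sample$transcripts)) {
    tx <- sample_transcripts(sample)
    f <- "points__transcripts.csv"
    utils::write.csv(tx, file.path(path, f), row.names = FALSE)
    add("points/transcripts", "points", f)
  }
  for (nm in names(sample$cells)) {
    keyt <- paste0("tables/cells_", nm)
    d <- flat_name(keyt)
    dir.create(file.path(path, d), showWarnings = FALSE)
    l <- sample$cells[[nm]]
    Matrix::writeMM(l$matrix, file.path(path, d, "matrix.mtx"))
    utils::write.csv(l$cell_table, file.path(path, d, "obs.csv"),
                     row.names = FALSE)
    utils::write.csv(l$feature_table, file.path(path, d, "var.csv"),
                     row.names = FALSE)
    add(keyt, "table", d)
    keys <- paste0("shapes/cells_", nm)
    f <- paste0(flat_name(keys), ".geojson")
    write_boundaries_geojson(l$boundaries, file.path(path, f))
    add(keys, "shapes", f)
  }
  for (nm in names(sample$units)) {
    keyt <- paste0("tables/units_", nm)
    d <- flat_name(keyt)
    dir.create(file.path(path, d), showWarnings = FALSE)
    l <- sample$units[[nm]]
    Matrix::writeMM(l$matrix, file.path(path, d, "matrix.mtx"))
    utils::write.csv(l$unit_table, file.path(path, d, "obs.csv"),
                     row.names = FALSE)
    utils::write.csv(l$feature_table, file.path(path, d, "var.csv"),
                     row.names = FALSE)
    add(keyt, "table", d)
    keys <- paste0("shapes/units_", nm)
    f <- paste0(flat_name(keys), ".geojson")
    write_shapes_geojson(l$shapes, file.path(path, f))
    add(keys, "shapes", f)
  }
  for (cat in c("annotations", "regions")) {
    for (nm in names(sample[[cat]])) {
      key <- sprintf("shapes/%s_%s", cat, nm)
      f <- paste0(flat_name(key), ".geojson")
      export_annotations_geojson(sample[[cat]][[nm]], file.path(path, f))
      add(key, "shapes", f)
    }
  }
  idx <- list(uid = sample$uid, metadata = sample$metadata,
              elements = elements)
  jsonlite::write_json(idx, file.path(path, "elements.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(elements)
}

fs_safe_key <- function(x) gsub("[^A-Za-z0-9_/.-]", "_", x)

#' Restore a sample from a flat export
#'
#' @param path directory written by [to_flat()].
#' @return A `spat_sample` with identical record counts and coordinates.
#' @export
from_flat <- function(path) {
  idx <- jsonlite::fromJSON(file.path(path, "elements.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  elements <- idx$elements
  keys <- names(elements) %||% character()
  images <- list(); cells <- list(); units <- list()
  annotations <- list(); regions <- list(); tx <- NULL

  pick <- function(prefix) keys[startsWith(keys, prefix)]

  for (key in pick("images/")) {
    nm <- sub("^images/", "", key)
    f <- elements[[key]]$files[[1L]]
    img <- open_image_tiff(file.path(path, f), name = nm)
    images[[nm]] <- img
  }
  if ("points/transcripts" %in% keys) {
    f <- elements[["points/transcripts"]]$files[[1L]]
    tx <- tibble::as_tibble(utils::read.csv(file.path(path, f),
                                            stringsAsFactors = FALSE))
  }
  read_table_element <- function(key) {
    d <- elements[[key]]$files[[1L]]
    m <- methods::as(Matrix::readMM(file.path(path, d, "matrix.mtx")),
                     "CsparseMatrix")
    obs <- tibble::as_tibble(utils::read.csv(file.path(path, d, "obs.csv"),
                                             stringsAsFactors = FALSE))
    var <- tibble::as_tibble(utils::read.csv(file.path(path, d, "var.csv"),
                                             stringsAsFactors = FALSE))
    list(m = m, obs = obs, var = var)
  }
  for (key in pick("tables/cells_")) {
    nm <- sub("^tables/cells_", "", key)
    e <- read_table_element(key)
    e$obs$cell_id <- as.character(e$obs$cell_id)
    bkey <- paste0("shapes/cells_", nm)
    b <- if (bkey %in% keys) {
      read_boundaries_geojson(file.path(path, elements[[bkey]]$files[[1L]]))
    } else NULL
    cells[[nm]] <- cell_layer(e$m, e$obs, e$var, b)
  }
  for (key in pick("tables/units_")) {
    nm <- sub("^tables/units_", "", key)
    e <- read_table_element(key)
    e$obs$unit_id <- as.character(e$obs$unit_id)
    skey <- paste0("shapes/units_", nm)
    sh <- read_shapes_geojson(file.path(path, elements[[skey]]$files[[1L]]))
    units[[nm]] <- unit_layer(e$m, e$obs, e$var, sh)
  }
  for (key in pick("shapes/annotations_")) {
    nm <- sub("^shapes/annotations_", "", key)
    annotations[[nm]] <- import_annotations_geojson(
      file.path(path, elements[[key]]$files[[1L]]), scope = "annotation")
  }
  for (key in pick("shapes/regions_")) {
    nm <- sub("^shapes/regions_", "", key)
    regions[[nm]] <- import_annotations_geojson(
      file.path(path, elements[[key]]$files[[1L]]), scope = "region")
  }
  md <- idx$metadata %||% list()
  if (!is.null(md$crop_offset)) md$crop_offset <- unlist(md$crop_offset)
  spat_sample(uid = idx$uid, metadata = md, images = images,
              transcripts = tx, cells = cells, units = units,
              annotations = annotations, regions = regions)
}
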