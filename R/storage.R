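#' On-disk project format with static/variable save semantics
#'
#' A project directory separates *static* data — raw images and transcript
#' locations, which never change during analysis — from *variable* data —
#' cell/unit tables, annotations, regions and metadata, which do:
#'
#' ```
#' project/
#'   manifest.json                  written last; inventory + checksums
#'   static/
#'     images/<name>.tif            plain or tiled multi-page TIFF
#'     images/<name>.json           sidecar: shape, pixel size, tiling
#'     transcripts.parquet|csv
#'   variable/
#'     metadata.json
#'     cells/<layer>/{matrix.mtx,cells.csv,features.csv,boundaries.geojson}
#'     units/<layer>/{matrix.mtx,units.csv,features.csv,shapes.geojson}
#'     annotations/<set>.geojson
#'     regions/<set>.geojson
#' ```
#'
#' [saveas_project()] writes everything and records a SHA-256 digest of
#' each static file in the manifest; [save_project()] rewrites only the
#' variable subtree, which keeps saves fast and static bytes untouched.
#' Loading is lazy for images and transcripts: opening a project reads
#' only the manifest and sidecars, payload bytes are read (and their
#' digests verified) on first access.
#'
#' @name project-format
NULL

manifest_name <- "manifest.json"

#' Save a sample or experiment to a new project directory
#'
#' @param x a `spat_sample` or `spat_experiment`.
#' @param root_path target directory (created; must be empty unless
#'   `overwrite`).
#' @param overwrite replace a non-empty target?
#' @return The manifest (for an experiment, list of manifests), invisibly.
#' @export
saveas_project <- function(x, root_path, overwrite = FALSE) {
  UseMethod("saveas_project")
}

#' @export
saveas_project.spat_experiment <- function(x, root_path, overwrite = FALSE) {
  prepare_root(root_path, overwrite)
  dir.create(file.path(root_path, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  manifests <- list()
  for (i in seq_len(n_samples(x))) {
    s <- x$samples[[i]]
    manifests[[s$uid]] <- saveas_project(
      s, file.path(root_path, "samples", s$uid), overwrite = TRUE)
  }
  utils::write.csv(x$metadata, file.path(root_path, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kind = "experiment", uids = x$metadata$uid),
    file.path(root_path, "experiment.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifests)
}

#' @export
saveas_project.spat_sample <- function(x, root_path, overwrite = FALSE) {
  prepare_root(root_path, overwrite)
  static_dir <- file.path(root_path, "static")
  var_dir <- file.path(root_path, "variable")
  dir.create(file.path(static_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(var_dir, recursive = TRUE, showWarnings = FALSE)

  inv <- list(images = list(), transcripts = NULL)
  for (nm in names(x$images)) {
    img <- x$images[[nm]]
    rel <- file.path("static", "images", paste0(fs_safe(nm), ".tif"))
    side <- write_image_tiff(img, file.path(root_path, rel))
    inv$images[[nm]] <- list(path = rel, sidecar = paste0(rel, ".json"),
                             pixel_size = img$pixel_size)
  }
  if (!is.null(x$transcripts)) {
    tx <- sample_transcripts(x)
    fmt <- if (requireNamespace("arrow", quietly = TRUE)) "parquet" else "csv"
    rel <- file.path("static", paste0("transcripts.", fmt))
    if (fmt == "parquet") {
      arrow::write_parquet(tx, file.path(root_path, rel))
    } else {
      utils::write.csv(tx, file.path(root_path, rel), row.names = FALSE)
    }
    inv$transcripts <- list(path = rel, format = fmt, n_rows = nrow(tx))
  }

  write_variable_tree(x, root_path)

  static_files <- list.files(static_dir, recursive = TRUE, full.names = FALSE)
  static_files <- file.path("static", static_files)
  checksums <- stats::setNames(
    lapply(static_files, function(p) {
      digest::digest(file.path(root_path, p), algo = "sha256", file = TRUE)
    }), static_files)

  manifest <- list(
    format_version = 1L, kind = "sample", uid = x$uid,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    updated = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    inventory = inv,
    layers = list(cells = as.list(names(x$cells)),
                  units = as.list(names(x$units)),
                  annotations = as.list(names(x$annotations)),
                  regions = as.list(names(x$regions))),
    static_checksums = checksums,
    crop_offset = as.list(x$metadata$crop_offset %||% NULL)
  )
  jsonlite::write_json(manifest, file.path(root_path, manifest_name),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

prepare_root <- function(root_path, overwrite) {
  if (dir.exists(root_path) && length(list.files(root_path, all.files = TRUE,
                                                 no.. = TRUE)) > 0L) {
    if (!overwrite) {
      stop(sprintf("target '%s' is not empty; pass overwrite = TRUE",
                   root_path), call. = FALSE)
    }
    unlink(root_path, recursive = TRUE)
  }
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
}

fs_safe <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

write_variable_tree <- function(x, root_path) {
  var_dir <- file.path(root_path, "variable")
  unlink(var_dir, recursive = TRUE)
  dir.create(var_dir, recursive = TRUE, showWarnings = FALSE)
  md <- x$metadata
  jsonlite::write_json(md, file.path(var_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(x$cells)) {
    d <- file.path(var_dir, "cells", fs_safe(nm))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    l <- x$cells[[nm]]
    Matrix::writeMM(l$matrix, file.path(d, "matrix.mtx"))
    utils::write.csv(l$cell_table, file.path(d, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(l$feature_table, file.path(d, "features.csv"),
                     row.names = FALSE)
    write_boundaries_geojson(l$boundaries, file.path(d, "boundaries.geojson"))
  }
  for (nm in names(x$units)) {
    d <- file.path(var_dir, "units", fs_safe(nm))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    l <- x$units[[nm]]
    Matrix::writeMM(l$matrix, file.path(d, "matrix.mtx"))
    utils::write.csv(l$unit_table, file.path(d, "units.csv"),
                     row.names = FALSE)
    utils::write.csv(l$feature_table, file.path(d, "features.csv"),
                     row.names = FALSE)
    write_shapes_geojson(l$shapes, file.path(d, "shapes.geojson"))
  }
  for (cat in c("annotations", "regions")) {
    d <- file.path(var_dir, cat)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(x[[cat]])) {
      export_annotations_geojson(x[[cat]][[nm]],
                                 file.path(d, paste0(fs_safe(nm), ".geojson")))
    }
  }
  invisible(NULL)
}

#' Save variable data into an existing project
#'
#' Rewrites only the variable subtree (cell/unit layers, annotations,
#' regions, metadata); files under `static/` are never touched, which the
#' recorded checksums guarantee. The manifest's `updated` timestamp and
#' layer inventory are refreshed.
#'
#' @param sample a `spat_sample` whose UID matches the project's.
#' @param project_path existing project directory.
#' @return The updated manifest, invisibly.
#' @export
save_project <- function(sample, project_path) {
  manifest <- read_manifest(project_path)
  if (!identical(manifest$uid, sample$uid)) {
    stop(sprintf("wrong project: manifest uid %s does not match sample uid %s",
                 manifest$uid, sample$uid), call. = FALSE)
  }
  write_variable_tree(sample, project_path)
  manifest$updated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  manifest$layers <- list(cells = as.list(names(sample$cells)),
                          units = as.list(names(sample$units)),
                          annotations = as.list(names(sample$annotations)),
                          regions = as.list(names(sample$regions)))
  manifest$crop_offset <- as.list(sample$metadata$crop_offset %||% NULL)
  jsonlite::write_json(manifest, file.path(project_path, manifest_name),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(project_path) {
  mp <- file.path(project_path, manifest_name)
  if (!file.exists(mp)) {
    stop(sprintf("'%s' is not a project (no manifest)", project_path),
         call. = FALSE)
  }
  jsonlite::fromJSON(mp, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Load a full sample from a project directory
#'
#' Images and transcripts come back as lazy handles — only the manifest
#' and image sidecars are read — while cells, units, annotations, regions
#' and metadata are materialized.
#'
#' @param project_path project directory written by [saveas_project()].
#' @return A `spat_sample`.
#' @export
load_sample <- function(project_path) {
  manifest <- read_manifest(project_path)
  images <- load_modality(project_path, "images", manifest = manifest)
  tx <- tryCatch(load_modality(project_path, "transcripts",
                               manifest = manifest),
                 error = function(e) NULL)
  cells <- load_modality(project_path, "cells", manifest = manifest)
  units <- load_modality(project_path, "units", manifest = manifest)
  ann <- load_modality(project_path, "annotations", manifest = manifest)
  reg <- load_modality(project_path, "regions", manifest = manifest)
  md <- jsonlite::fromJSON(file.path(project_path, "variable",
                                     "metadata.json"),
                           simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!is.null(md$crop_offset)) md$crop_offset <- unlist(md$crop_offset)
  spat_sample(uid = manifest$uid, metadata = md, images = images,
              transcripts = tx, cells = cells, units = units,
              annotations = ann, regions = reg)
}

#' Load one data category from a project
#'
#' @param project_path project directory.
#' @param category one of `"images"`, `"transcripts"`, `"cells"`,
#'   `"units"`, `"annotations"`, `"regions"`.
#' @param layer_name optional layer/set/image name; when given, the single
#'   object is returned instead of the named list.
#' @param manifest pre-read manifest (internal use).
#' @return Lazy `pixel_image`(s) or `lazy_table` for images/transcripts;
#'   materialized `cell_layer`/`unit_layer`/`polygon_set`(s) otherwise.
#' @export
load_modality <- function(project_path, category, layer_name = NULL,
                          manifest = NULL) {
  cats <- c("images", "transcripts", "cells", "units", "annotations",
            "regions")
  if (!category %in% cats) {
    stop(sprintf("unknown category '%s' (expected one of %s)", category,
                 paste(cats, collapse = ", ")), call. = FALSE)
  }
  manifest <- manifest %||% read_manifest(project_path)
  out <- switch(
    category,
    images = {
      imgs <- list()
      for (nm in names(manifest$inventory$images)) {
        e <- manifest$inventory$images[[nm]]
        imgs[[nm]] <- open_image_tiff(
          file.path(project_path, e$path), name = nm,
          sha256 = manifest$static_checksums[[e$path]])
      }
      imgs
    },
    transcripts = {
      e <- manifest$inventory$transcripts
      if (is.null(e)) stop("project has no transcripts", call. = FALSE)
      path <- file.path(project_path, e$path)
      reader <- if (identical(e$format, "parquet")) {
        function() arrow::read_parquet(path)
      } else {
        function() utils::read.csv(path, stringsAsFactors = FALSE)
      }
      new_lazy_table(reader, e$n_rows,
                     checksum = list(path = path,
                                     sha256 = manifest$static_checksums[[e$path]]))
    },
    cells = load_table_layers(project_path, "cells", manifest),
    units = load_table_layers(project_path, "units", manifest),
    annotations = load_polygon_sets(project_path, "annotations", manifest),
    regions = load_polygon_sets(project_path, "regions", manifest)
  )
  if (!is.null(layer_name)) {
    if (category == "transcripts") return(out)
    if (!layer_name %in% names(out)) {
      stop(sprintf("unknown layer '%s' in category '%s'", layer_name,
                   category), call. = FALSE)
    }
    return(out[[layer_name]])
  }
  out
}

load_table_layers <- function(project_path, category, manifest) {
  layers <- list()
  for (nm in unlist(manifest$layers[[category]])) {
    d <- file.path(project_path, "variable", category, fs_safe(nm))
    m <- methods::as(Matrix::readMM(file.path(d, "matrix.mtx")),
                     "CsparseMatrix")
    feats <- tibble::as_tibble(utils::read.csv(file.path(d, "features.csv"),
                                               stringsAsFactors = FALSE))
    if (category == "cells") {
      ct <- tibble::as_tibble(utils::read.csv(file.path(d, "cells.csv"),
                                              stringsAsFactors = FALSE))
      ct$cell_id <- as.character(ct$cell_id)
      b <- read_boundaries_geojson(file.path(d, "boundaries.geojson"))
      layers[[nm]] <- cell_layer(m, ct, feats, b)
    } else {
      ut <- tibble::as_tibble(utils::read.csv(file.path(d, "units.csv"),
                                              stringsAsFactors = FALSE))
      ut$unit_id <- as.character(ut$unit_id)
      sh <- read_shapes_geojson(file.path(d, "shapes.geojson"))
      layers[[nm]] <- unit_layer(m, ut, feats, sh)
    }
  }
  layers
}

load_polygon_sets <- function(project_path, category, manifest) {
  scope <- if (category == "annotations") "annotation" else "region"
  sets <- list()
  for (nm in unlist(manifest$layers[[category]])) {
    p <- file.path(project_path, "variable", category,
                   paste0(fs_safe(nm), ".geojson"))
    sets[[nm]] <- import_annotations_geojson(p, scope = scope)
  }
  sets
}

# ---- TIFF image I/O ------------------------------------------------------

# Write a pixel_image as TIFF; images larger than tile_px in either
# dimension are written as a tiled multi-page TIFF (pages are row-major
# tiles) so windows can be read without decoding the full image. A JSON
# sidecar records shape, pixel size, intensity scale and tiling.
write_image_tiff <- function(img, path, tile_px = 1024L) {
  px <- img_pixels(img)
  mx <- max(px, 1)
  integral <- all(px == round(px)) && min(px) >= 0
  if (integral && mx <= 255) {
    bits <- 8L; maxval <- 255
  } else if (integral && mx <= 65535) {
    bits <- 16L; maxval <- 65535
  } else {
    bits <- 32L; maxval <- mx
  }
  h <- dim(px)[1L]; w <- dim(px)[2L]
  tiled <- (h > tile_px || w > tile_px)
  norm <- px / maxval
  if (tiled) {
    wins <- iter_tiles(c(h, w), tile_spec(tile_px))
    pages <- lapply(seq_len(nrow(wins)), function(i) {
      index_region(norm, wins$r0[i], wins$c0[i], wins$h[i], wins$w[i])
    })
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(norm, path, bits.per.sample = bits)
  }
  side <- list(name = img$name, pixel_size = img$pixel_size,
               origin = img$origin %||% c(0, 0),
               shape = dim(px), channel_names = img$channel_names,
               bits = bits, maxval = maxval, tiled = tiled,
               tile_px = if (tiled) tile_px else NULL)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(side)
}

# Open a saved TIFF lazily: reads only the sidecar. Payload reads verify
# the recorded SHA-256 on first access.
open_image_tiff <- function(path, name = NULL, sha256 = NULL) {
  side <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(side$shape)
  maxval <- side$maxval
  restore <- function(a) {
    v <- a * maxval
    if (side$bits < 32L) v <- round(v)
    v
  }
  assemble <- function() {
    if (isTRUE(side$tiled)) {
      pages <- tiff::readTIFF(path, all = TRUE)
      wins <- iter_tiles(shape[1:2], tile_spec(side$tile_px))
      full <- array(0, dim = shape)
      for (i in seq_len(nrow(wins))) {
        pg <- img_canonical_array(pages[[i]])
        if (length(shape) == 3L) {
          full[wins$r0[i]:(wins$r0[i] + wins$h[i] - 1L),
               wins$c0[i]:(wins$c0[i] + wins$w[i] - 1L), ] <- pg
        } else {
          full[wins$r0[i]:(wins$r0[i] + wins$h[i] - 1L),
               wins$c0[i]:(wins$c0[i] + wins$w[i] - 1L)] <- pg
        }
      }
      restore(full)
    } else {
      restore(img_canonical_array(tiff::readTIFF(path)))
    }
  }
  region_reader <- NULL
  if (isTRUE(side$tiled)) {
    wins <- iter_tiles(shape[1:2], tile_spec(side$tile_px))
    region_reader <- function(r0, c0, h, w) {
      r1 <- r0 + h - 1L; c1 <- c0 + w - 1L
      hit <- which(wins$r0 <= r1 & (wins$r0 + wins$h - 1L) >= r0 &
                     wins$c0 <= c1 & (wins$c0 + wins$w - 1L) >= c0)
      out_dim <- if (length(shape) == 3L) c(h, w, shape[3L]) else c(h, w)
      out <- array(0, dim = out_dim)
      pages <- tiff::readTIFF(path, all = hit)
      if (!is.list(pages)) pages <- list(pages)
      for (k in seq_along(hit)) {
        i <- hit[k]
        pg <- img_canonical_array(pages[[k]])
        rr <- max(wins$r0[i], r0):min(wins$r0[i] + wins$h[i] - 1L, r1)
        cc <- max(wins$c0[i], c0):min(wins$c0[i] + wins$w[i] - 1L, c1)
        src <- index_region(pg, rr[1L] - wins$r0[i] + 1L,
                            cc[1L] - wins$c0[i] + 1L,
                            length(rr), length(cc))
        if (length(shape) == 3L) {
          out[rr - r0 + 1L, cc - c0 + 1L, ] <- src
        } else {
          out[rr - r0 + 1L, cc - c0 + 1L] <- src
        }
      }
      restore(out)
    }
  }
  lazy_pixel_image(
    shape = shape, pixel_size = side$pixel_size,
    reader = assemble, region_reader = region_reader,
    channel_names = side$channel_names,
    name = name %||% side$name, origin = side$origin %||% c(0, 0),
    checksum = if (!is.null(sha256)) list(path = path, sha256 = sha256))
}

#' Load an experiment saved by [saveas_project()]
#' @param root_path experiment project directory.
#' @return A `spat_experiment`.
#' @export
load_experiment <- function(root_path) {
  ej <- jsonlite::fromJSON(file.path(root_path, "experiment.json"))
  meta <- tibble::as_tibble(utils::read.csv(file.path(root_path,
                                                      "metadata.csv"),
                                            stringsAsFactors = FALSE,
                                            check.names = FALSE))
  samples <- lapply(ej$uids, function(u) {
    load_sample(file.path(root_path, "samples", u))
  })
  spat_experiment(samples, meta)
}
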