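#' Multi-sample experiment container
#'
#' A `spat_experiment` stores an ordered list of [spat_sample()] objects
#' joined to a metadata tibble by UID: row i of the metadata table describes
#' sample i, and the `uid` column is the sole join key. Experiments can be
#' assembled sample by sample ([add_sample()]), by splitting one sample
#' along its region polygons ([from_regions()]), or from a configuration
#' file listing project directories and metadata ([from_config()]).
#'
#' @param samples list of `spat_sample`s with distinct UIDs.
#' @param metadata tibble with one row per sample; a `uid` column is added
#'   (and checked) automatically.
#' @return A `spat_experiment`.
#' @export
spat_experiment <- function(samples = list(), metadata = NULL) {
  uids <- vapply(samples, sample_uid, "")
  if (anyDuplicated(uids)) {
    stop(sprintf("uid collision: %s",
                 paste(unique(uids[duplicated(uids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- tibble::tibble(uid = uids)
  } else {
    metadata <- tibble::as_tibble(metadata)
    if (!"uid" %in% names(metadata)) metadata$uid <- uids
    stopifnot(nrow(metadata) == length(samples), identical(metadata$uid, uids))
    metadata <- dplyr::relocate(metadata, "uid")
  }
  structure(list(samples = samples, metadata = metadata),
            class = "spat_experiment")
}

#' @export
print.spat_experiment <- function(x, ...) {
  cat(sprintf("<spat_experiment: %d sample(s)>\n", n_samples(x)))
  if (n_samples(x) > 0L) print(x$metadata)
  invisible(x)
}

#' @rdname spat_experiment
#' @param x a `spat_experiment`.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname spat_experiment
#' @export
experiment_metadata <- function(x) x$metadata

#' Append a sample and its metadata row to an experiment
#'
#' @param experiment a `spat_experiment`.
#' @param sample a `spat_sample`; a fresh UID is minted if it has none.
#' @param metadata_row named list or one-row data frame of metadata values;
#'   the `uid` column is set from the sample.
#' @return The grown `spat_experiment`.
#' @export
add_sample <- function(experiment, sample, metadata_row = list()) {
  if (is.null(sample$uid) || is.na(sample$uid) || !nzchar(sample$uid)) {
    sample$uid <- mint_uid()
  }
  if (sample$uid %in% experiment$metadata$uid) {
    stop(sprintf("uid collision: %s already present", sample$uid),
         call. = FALSE)
  }
  row <- tibble::as_tibble(as.list(metadata_row))
  if (nrow(row) == 0L) row <- tibble::tibble(.rows = 1L)
  row$uid <- sample$uid
  row <- dplyr::relocate(row, "uid")
  meta <- dplyr::bind_rows(experiment$metadata, row)
  spat_experiment(c(experiment$samples, list(sample)), meta)
}

#' Filter an experiment by a predicate over metadata columns
#'
#' Samples whose metadata row satisfies the predicate are kept, in their
#' stored order; the samples themselves are shared (views), not copied, so
#' in-place edits propagate to the parent experiment.
#'
#' @param experiment a `spat_experiment`.
#' @param ... filter expressions over metadata columns, as in
#'   [dplyr::filter()]. Referencing an unknown column is an error.
#' @return A `spat_experiment` with the matching subset (possibly empty).
#' @export
query <- function(experiment, ...) {
  meta <- experiment$metadata
  meta$.row <- seq_len(nrow(meta))
  quos <- rlang::enquos(...)
  for (q in quos) {
    for (v in all.vars(rlang::quo_get_expr(q))) {
      if (!v %in% names(meta) && !exists(v, envir = rlang::quo_get_env(q))) {
        stop(sprintf("unknown metadata column '%s'", v), call. = FALSE)
      }
    }
  }
  kept <- dplyr::filter(meta, !!!quos)
  idx <- kept$.row
  kept$.row <- NULL
  spat_experiment(experiment$samples[idx], kept)
}

#' Iterate over (metadata row, sample) pairs in stored order
#'
#' @param experiment a `spat_experiment`.
#' @return List of `list(metadata = <one-row tibble>, sample =
#'   <spat_sample>)`, one element per sample; `metadata$uid` matches
#'   `sample_uid(sample)` in every pair.
#' @export
iterate <- function(experiment) {
  lapply(seq_len(n_samples(experiment)), function(i) {
    list(metadata = experiment$metadata[i, , drop = FALSE],
         sample = experiment$samples[[i]])
  })
}

#' Concatenate experiments
#'
#' Samples and metadata rows are concatenated in input order; metadata
#' columns are unioned, with NA marking values absent from an input.
#'
#' @param experiments list of `spat_experiment`s with globally distinct
#'   UIDs.
#' @return One `spat_experiment`.
#' @export
concat <- function(experiments) {
  stopifnot(all(vapply(experiments, inherits, TRUE, "spat_experiment")))
  uids <- unlist(lapply(experiments, function(e) e$metadata$uid))
  if (anyDuplicated(uids)) {
    stop(sprintf("uid collision: %s",
                 paste(unique(uids[duplicated(uids)]), collapse = ", ")),
         call. = FALSE)
  }
  meta <- dplyr::bind_rows(lapply(experiments, experiment_metadata))
  samples <- do.call(c, lapply(experiments, function(e) e$samples))
  spat_experiment(samples %||% list(), meta)
}

#' Split a sample into an experiment along its region polygons
#'
#' One cropped sample per polygon of the named region set (TMA cores,
#' sections), cropped with `shift_origin = TRUE` so each child starts at
#' its own origin. Child metadata carries the parent UID, the region name
#' and class, and an `empty` flag for regions that retained no cells.
#'
#' @param sample a `spat_sample` with a region set `region_set_name`.
#' @param region_set_name name of the region polygon set to split along.
#' @return A `spat_experiment` with one sample per region.
#' @export
from_regions <- function(sample, region_set_name) {
  if (!region_set_name %in% names(sample$regions)) {
    stop(sprintf("unknown region set '%s'", region_set_name), call. = FALSE)
  }
  rs <- sample$regions[[region_set_name]]
  if (nrow(rs) == 0L) {
    warning("region set is empty; returning empty experiment", call. = FALSE)
    return(spat_experiment())
  }
  exp <- spat_experiment()
  for (i in seq_len(nrow(rs))) {
    child <- withCallingHandlers(
      crop_sample(sample, rs$coords[[i]], shift_origin = TRUE),
      warning = function(w) invokeRestart("muffleWarning"))
    child$uid <- mint_uid()
    nc <- sum(vapply(child$cells, n_cells, 0L))
    exp <- add_sample(exp, child,
                      list(parent_uid = sample_uid(sample),
                           region_name = rs$name[i],
                           region_class = rs$class_label[i],
                           empty = nc == 0L))
  }
  exp
}

#' Assemble an experiment from a configuration file
#'
#' The configuration is a CSV with a required `path` column pointing at
#' saved project directories (relative paths resolve against the config
#' file's directory); every other column becomes experiment metadata.
#'
#' @param config_path path to the CSV configuration file.
#' @return A `spat_experiment` with one loaded sample per row.
#' @export
from_config <- function(config_path) {
  cfg <- utils::read.csv(config_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"path" %in% names(cfg)) {
    stop("config error: required column 'path' is missing", call. = FALSE)
  }
  base <- dirname(normalizePath(config_path))
  exp <- spat_experiment()
  for (i in seq_len(nrow(cfg))) {
    p <- cfg$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    s <- tryCatch(load_sample(p), error = function(e) {
      stop(sprintf("load error at config row %d (%s): %s",
                   i, cfg$path[i], conditionMessage(e)), call. = FALSE)
    })
    md <- as.list(cfg[i, setdiff(names(cfg), "path"), drop = FALSE])
    md$path <- cfg$path[i]
    exp <- add_sample(exp, s, md)
  }
  exp
}
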