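#' Save and load clVAE checkpoints
#'
#' A trained clVAE is small (a few hundred parameters), so checkpoints are
#' stored as a single JSON document: configuration, encoder/decoder weight
#' matrices, and the training-loss trace. Reloading reproduces scores to
#' full double precision (the decimal serialization can differ from the
#' in-memory value in the last binary digit).
#'
#' @param model A `trained_clvae`.
#' @param path JSON file path.
#' @return `save_clvae` returns `path` invisibly; `load_clvae` the restored
#'   `trained_clvae`.
#' @export
save_clvae <- function(model, path) {
  stopifnot(inherits(model, "trained_clvae"))
  cfg <- model$config
  params <- lapply(model$params, function(p)
    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
    else list(dim = NULL, data = as.vector(p)))
  jsonlite::write_json(
    list(config = unclass(cfg), params = params,
         loss_trace = model$loss_trace),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_clvae
#' @export
load_clvae <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- x$config
  cfg <- do.call(vae_config, cfg_args[!vapply(cfg_args, is.null, logical(1))])
  params <- lapply(x$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = cfg,
                 loss_trace = as.numeric(x$loss_trace)),
            class = "trained_clvae")
}

#' Read a dataset manifest
#'
#' A manifest is a YAML list of entries, each with `frame` (image path),
#' `mask` (ROI mask path, optional: missing means the whole frame),
#' `label` (`positive`/`negative`), optional `concentration` (ug/mL) and
#' optional `id`. Paths are resolved relative to the manifest's directory.
#'
#' @param path YAML manifest path.
#' @return List of manifest entries with resolved paths.
#' @export
read_dataset_manifest <- function(path) {
  entries <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  lapply(entries, function(e) {
    e$frame <- file.path(base, e$frame)
    if (!is.null(e$mask)) e$mask <- file.path(base, e$mask)
    e
  })
}

#' Load the labeled pixel pools a manifest describes
#'
#' @param manifest Entries from [read_dataset_manifest()].
#' @return List with labeled pixel sets `positive` and `negative`.
#' @export
load_manifest_pixels <- function(manifest) {
  pools <- lapply(manifest, function(e) {
    frame <- read_frame(e$frame)
    mask <- if (is.null(e$mask)) matrix(TRUE, dim(frame)[1], dim(frame)[2])
            else read_mask(e$mask)
    extract_roi_pixels(frame, mask, e$label,
                       concentration = e$concentration %||% NA_real_,
                       frame_id = e$id %||% basename(e$frame))
  })
  labels <- vapply(pools, function(p) p$label[1], character(1))
  list(positive = do.call(rbind, pools[labels == "positive"]),
       negative = do.call(rbind, pools[labels == "negative"]))
}

#' Write a numeric map as a TSV container
#'
#' Concentration and score maps are float planes; they are persisted as
#' plain tab-separated matrices (one row per pixel row) with a `#`-comment
#' header carrying the dimensions — a documented, text-only container.
#'
#' @param map Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly; `read_float_map` returns the matrix.
#' @export
write_float_map <- function(map, path) {
  stopifnot(is.matrix(map))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# float map %d x %d", nrow(map), ncol(map)), con)
  utils::write.table(map, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_float_map
#' @export
read_float_map <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
}
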