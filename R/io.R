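# Image and scene I/O: TIFF stacks plus JSON manifests.

#' Read a TIFF image or stack
#'
#' @param path File path.
#' @return A matrix for a single page, a list of matrices for a stack.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L) pages[[1L]] else pages
}

#' Write a TIFF image or stack
#'
#' @param image Matrix or list of matrices with values in `[0, 1]`.
#' @param path File path.
#' @param bits Bits per sample: 8, 16, or 32 (quantized integer
#'   samples; 32-bit resolves ~2e-10 intensity steps).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 32L) {
  tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write / read a synthetic scene
#'
#' A scene is stored as `<stem>.tif` (32-bit pages: bright-field then the
#' fluorescence channels), `<stem>_labels.tif` (16-bit label mask) and
#' `<stem>.json` (spec, channel order, pixel size, ground-truth table).
#'
#' @param scene A `scene_pair`.
#' @param stem Path stem (no extension).
#' @return `write_scene` returns `stem` invisibly; `read_scene` the
#'   reconstructed `scene_pair`.
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "scene_pair"))
  pages <- c(list(scene$brightfield), unname(scene$channels))
  tiff::writeTIFF(pages, paste0(stem, ".tif"), bits.per.sample = 32L)
  tiff::writeTIFF(scene$labels / 65535, paste0(stem, "_labels.tif"),
                  bits.per.sample = 16L)
  jsonlite::write_json(
    list(spec = unclass(scene$spec),
         channels = names(scene$channels),
         truth = scene$truth),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  man <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(stem, ".tif"), all = TRUE)
  labels <- round(tiff::readTIFF(paste0(stem, "_labels.tif")) * 65535)
  storage.mode(labels) <- "integer"
  spec <- do.call(scene_spec, man$spec)
  channels <- pages[-1L]
  names(channels) <- man$channels
  structure(list(brightfield = pages[[1L]], channels = channels,
                 labels = labels, truth = as.data.frame(man$truth),
                 spec = spec),
            class = "scene_pair")
}
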