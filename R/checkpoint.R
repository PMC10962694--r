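## Checkpoint serialization. A checkpoint is a single versioned RDS archive
## holding the specification, parameter arrays, standardization constants,
## level tables and seed; loading reproduces predictions bit-for-bit.

#' Save a fitted model or ensemble to a checkpoint file
#'
#' @param object a `cdrnn_fit` or `cdrnn_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
cdrnn_save <- function(object, path) {
  stopifnot(inherits(object, c("cdrnn_fit", "cdrnn_ensemble")))
  saveRDS(list(format = "cdrnn_checkpoint", format_version = 1L,
               package_version = as.character(utils::packageVersion("cdrnn")),
               object = object),
          path)
  invisible(path)
}

#' Load a checkpoint written by [cdrnn_save()]
#'
#' @param path checkpoint file path.
#' @return the stored `cdrnn_fit` or `cdrnn_ensemble`.
#' @export
cdrnn_load <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "cdrnn_checkpoint")) {
    stop("not a model checkpoint: ", path)
  }
  if (x$format_version > 1L) {
    stop("checkpoint format version ", x$format_version, " is too new")
  }
  x$object
}
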