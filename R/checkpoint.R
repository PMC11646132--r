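#' Save a model checkpoint
#'
#' Single-file checkpoint holding the configuration, all weights, the
#' initialisation seed and the training history.
#'
#' @param model an `m6a_model`.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(config = model$config, params = model$params,
               init_seed = model$init_seed, history = model$history,
               format = 1L),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return an `m6a_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (is.null(x$config) || is.null(x$params))
    stop("not a model checkpoint: ", path)
  structure(list(config = x$config, params = x$params,
                 init_seed = x$init_seed, history = x$history),
            class = "m6a_model")
}

#' Write predictions as TSV
#'
#' @param predictions data.frame from [predict.m6a_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
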