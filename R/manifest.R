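#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialized form; alongside it a portable
#' JSON weight manifest (layer name to shape, plus the parameter count) is
#' written for audit.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`); the manifest is written next to it
#'   with suffix `.manifest.json`.
#' @return `path`, invisibly.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  manifest <- list(
    parameters = count_parameters(model),
    input_length = model$config$input_length,
    in_channels = model$config$in_channels,
    layers = lapply(model$params, function(p) {
      if (is.matrix(p)) dim(p) else length(p)
    })
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) {
    vcg_abort("checkpoint does not contain a unet_model", "vcg_io_error")
  }
  model
}

#' Write a run manifest next to a command's outputs
#'
#' Records the command, resolved configuration, seed, input/output paths,
#' package version and timestamp, so a run can be reproduced from its
#' manifest.
#'
#' @param command command name.
#' @param config named list of resolved settings.
#' @param seed integer seed.
#' @param inputs,outputs character vectors of paths.
#' @param path manifest destination (JSON).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(command, config, seed, inputs, outputs, path) {
  jsonlite::write_json(
    list(
      command = command,
      config = config,
      seed = seed,
      inputs = inputs,
      outputs = outputs,
      package_version = as.character(utils::packageVersion("vcgrpeak")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
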