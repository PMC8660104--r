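#' Read a simulation configuration from JSON
#'
#' The JSON document may contain any of the blocks `neural`, `arena`,
#' `camera`, `agent`, `sweep` and `protocol`; each block's entries are
#' passed to the matching constructor ([network_config()],
#' [default_arena()], [camera_config()], [agent_config()],
#' [sweep_config()], [trial_protocol()]), with constructor defaults
#' filling anything omitted.
#'
#' @param path Path to the JSON file.
#' @return A list with elements `neural`, `arena`, `camera`, `agent`,
#'   `sweep`, `protocol`.
#' @export
load_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  build <- function(block, ctor) {
    args <- doc[[block]]
    if (is.null(args)) args <- list()
    do.call(ctor, as.list(args))
  }
  list(
    neural = build("neural", network_config),
    arena = build("arena", default_arena),
    camera = build("camera", camera_config),
    agent = build("agent", agent_config),
    sweep = build("sweep", sweep_config),
    protocol = build("protocol", trial_protocol)
  )
}

#' Write a simulation configuration to JSON
#'
#' @param config A list as returned by [load_config()] (any subset of
#'   blocks).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  doc <- lapply(config, function(block) {
    if (is.list(block)) unclass(block) else block
  })
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
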