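#' Save and restore heart configurations as JSON
#'
#' Serializes a [heart_config()] (all parameter vectors, the patch table,
#' toggles, timing and initial volumes) to a JSON document carrying a
#' schema version, and reads it back. Values round-trip at full printed
#' double precision (~16 significant digits).
#'
#' @param config a [heart_config()].
#' @param path file path.
#' @return `write_heart_config()` returns `path` invisibly;
#'   `read_heart_config()` returns a `cardiomef_config`.
#' @export
write_heart_config <- function(config, path) {
  stopifnot(inherits(config, "cardiomef_config"))
  doc <- list(
    schema = "cardiomef-config-1",
    cell = as.list(unclass(config$cell)),
    sac = as.list(unclass(config$sac)),
    land = as.list(unclass(config$land)),
    passive = as.list(unclass(config$passive)),
    circ = as.list(unclass(config$circ)),
    toggles = as.list(unclass(config$toggles)),
    timing = as.list(config$timing),
    init = as.list(config$init),
    patches = config$patches
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heart_config
#' @export
read_heart_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "cardiomef-config-1"))
    abort(paste("unsupported configuration schema:", doc$schema))
  vec <- function(x, cls) structure(unlist(x), class = c(cls, "numeric"))
  structure(list(
    cell = vec(doc$cell, "cardiomef_cell_params"),
    sac = vec(doc$sac, "cardiomef_sac_params"),
    land = vec(doc$land, "cardiomef_land_params"),
    passive = vec(doc$passive, "cardiomef_passive_params"),
    circ = vec(doc$circ, "cardiomef_circ_params"),
    toggles = vec(doc$toggles, "cardiomef_toggles"),
    timing = unlist(doc$timing),
    init = unlist(doc$init),
    patches = as_tibble(doc$patches)
  ), class = "cardiomef_config")
}
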