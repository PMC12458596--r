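#' Persist a resolved scene
#'
#' The per-bin visual attributes are written as an Arrow IPC (Feather)
#' table; link segments go to a JSON sidecar at `<path>.links.json`
#' together with the scene's default radius.
#'
#' @param scene a `resolved_scene`.
#' @param path output path for the marks table.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "resolved_scene"))
  arrow::write_feather(scene$marks, path)
  jsonlite::write_json(list(default_radius = scene$default_radius,
                            links = scene$links),
                       paste0(path, ".links.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  marks <- as.data.frame(arrow::read_feather(path))
  side <- jsonlite::fromJSON(paste0(path, ".links.json"))
  links <- as.data.frame(side$links)
  if (!nrow(links))
    links <- data.frame(from = integer(), to = integer(),
                        x0 = numeric(), y0 = numeric(), z0 = numeric(),
                        x1 = numeric(), y1 = numeric(), z1 = numeric())
  structure(list(marks = marks, links = links,
                 default_radius = side$default_radius),
            class = "resolved_scene")
}
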