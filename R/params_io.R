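# Model parameter serialization: a JSON manifest (names, shapes) with the
# flattened values, written as plain text. Round-trip preserves full double
# precision.

#' Save / load fusion-model parameters
#'
#' @param params parameter list from [init_fusion_params()] (possibly
#'   trained)
#' @param path output JSON path
#' @return `path` invisibly (save) or the parameter list (load)
#' @export
params_save <- function(params, path) {
  payload <- lapply(params, function(x) {
    list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.numeric(x))
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname params_save
#' @export
params_load <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(entry) {
    d <- unlist(entry$dim)
    v <- as.numeric(unlist(entry$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  })
  structure(out, class = "np_params")
}
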