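## Flat key-value parameter files.  Lines are "key: value" (vectors
## comma-separated); '#' starts a comment.  The bundled reference file
## inst/extdata/spiking-hek-reference.cfg carries the calibrated defaults.

.parse_kv <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1])
  vals <- lapply(kv, function(m) as.numeric(strsplit(m[3], ",")[[1]]))
  names(vals) <- vapply(kv, function(m) trimws(m[2]), character(1))
  vals
}

#' Read and write cell-parameter files
#'
#' Flat key-value text serialisation of a [cell_params()] object; the
#' package ships the calibrated reference cell as
#' `system.file("extdata", "spiking-hek-reference.cfg", package =
#' "optospike")`.
#'
#' @param path File path.
#' @return `read_cell_params` returns a [cell_params()];
#'   `write_cell_params` returns `path` invisibly.
#' @examples
#' ref <- read_cell_params(system.file("extdata",
#'   "spiking-hek-reference.cfg", package = "optospike"))
#' @export
read_cell_params <- function(path) {
  vals <- .parse_kv(path)
  do.call(cell_params, vals)
}

#' @rdname read_cell_params
#' @param cell A [cell_params()] object.
#' @export
write_cell_params <- function(cell, path) {
  keys <- names(unclass(cell))
  lines <- vapply(keys, function(k)
    sprintf("%s: %s", k, paste(format(cell[[k]], digits = 15),
                               collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
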