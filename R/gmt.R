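#' Read gene sets from a GMT file
#'
#' Thin wrapper around [fgsea::gmtPathways()] returning a named list of
#' character vectors.
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then member genes).
#' @return Named list of unique gene symbol vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (or a single character vector
#'   together with `name`).
#' @param path Output path.
#' @param name Set name used when `sets` is a bare character vector.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, name = "geneset") {
  if (is.character(sets)) {
    sets <- setNames(list(sets), name)
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
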