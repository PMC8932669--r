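#' Read and write outline coordinate files
#'
#' Outlines are exchanged as two-column CSV files (`x`, `y`, header row, one
#' vertex per row, first vertex not repeated). All tabular results in the
#' package (coefficient tables, performance tables, landscapes, per-bin
#' disparity) are plain tibbles and can be written with
#' [utils::write.csv()] directly.
#'
#' @param outline A `jaw_outline`.
#' @param path File path.
#' @return `read_outline_csv()` returns a `jaw_outline`;
#'   `write_outline_csv()` returns `path` invisibly.
#' @export
write_outline_csv <- function(outline, path) {
  outline <- as_outline(outline, enforce_ccw = FALSE)
  utils::write.csv(as.data.frame(outline[, c("x", "y")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  as_outline(utils::read.csv(path), enforce_ccw = FALSE)
}
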