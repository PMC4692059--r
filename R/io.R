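# Plain-text I/O: deterministic TSV writers and SEG-style segment files.
# All interval coordinates at file boundaries are 1-based inclusive.

#' Write a tibble as a deterministic TSV
#'
#' Tab-separated, no quoting, no row names, fixed column order as given;
#' repeated runs produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_deterministic <- function(df, path) {
  df <- as.data.frame(df)
  listcols <- vapply(df, is.list, logical(1))
  for (cl in names(df)[listcols]) {
    df[[cl]] <- vapply(df[[cl]], paste, character(1), collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write segments in SEG-style format
#'
#' Columns `sample`, `chrom`, `start_bp`, `end_bp`, `n_markers`,
#' `seg_mean`; a comment header documents the 1-based inclusive
#' coordinate convention.
#'
#' @param segments Segment tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_seg <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SEG-style segments; coordinates 1-based inclusive", con)
  utils::write.table(
    as.data.frame(segments[, c("sample", "chrom", "start_bp", "end_bp",
                               "n_markers", "seg_mean")]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    eol = "\n")
  invisible(path)
}

#' Read a SEG-style segment file written by [write_seg()]
#'
#' @param path File path.
#' @return Segment tibble.
#' @export
read_seg <- function(path) {
  as_tibble(read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}
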