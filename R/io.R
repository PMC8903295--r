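#' Read and write modification sequences as compact text
#'
#' Sequences travel as plain text, one sequence per line, each position a
#' single character `0`, `1` or `2`. Lines may have different lengths.
#'
#' @param path File path.
#' @return For `read_sequences`, a list of integer vectors.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences in file", call. = FALSE)
  lapply(seq_along(lines), function(i) {
    chars <- strsplit(lines[[i]], "", fixed = TRUE)[[1]]
    if (!all(chars %in% c("0", "1", "2")))
      stop(sprintf("line %d: sequences may contain only 0/1/2", i),
           call. = FALSE)
    as.integer(chars)
  })
}

#' @rdname read_sequences
#' @param sequences A list of integer vectors (or a single vector) over
#'   \{0, 1, 2\}.
#' @return For `write_sequences`, the path, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  if (!is.list(sequences)) sequences <- list(sequences)
  lines <- vapply(sequences, function(x) {
    x <- assert_ternary(x, "sequences")
    paste(x, collapse = "")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an occupancy track as 2-column TSV
#'
#' @param track An `occupancy_track` data frame (or numeric vector of
#'   values, indexed 1..N).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_track <- function(track, path) {
  v <- track_values(track)
  pos <- if (is.data.frame(track) && "pos" %in% names(track)) track$pos
         else seq_along(v)
  utils::write.table(data.frame(pos, v), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
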