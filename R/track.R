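#' Read a per-nucleosome occupancy track
#'
#' Reads population-averaged modification occupancy from a bedGraph file
#' (4 columns: chrom, start, end, value; 0-based half-open intervals; parsed
#' with \pkg{rtracklayer}) or a 2-column TSV (index, value). Intervals map
#' to consecutive nucleosome indices in file order; strand is ignored
#' (occupancy is strandless).
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.bedgraph`/`.bg` vs anything
#'   else), `"bedgraph"` or `"tsv"`.
#' @return A data frame of class `"occupancy_track"` with columns `pos`
#'   (nucleosome index) and `value`, plus `chrom`, `start`, `end` for
#'   bedGraph input.
#' @export
read_track <- function(path, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  if (format == "bedgraph") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading bedGraph requires the 'rtracklayer' package",
           call. = FALSE)
    gr <- as.data.frame(rtracklayer::import(path, format = "bedGraph"))
    tr <- data.frame(pos = seq_len(nrow(gr)),
                     chrom = as.character(gr$seqnames),
                     start = gr$start - 1L,   # back to 0-based half-open
                     end = gr$end,
                     value = gr$score)
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             col.names = c("pos", "value"),
                             colClasses = "character")
    pos <- suppressWarnings(as.integer(raw$pos))
    value <- suppressWarnings(as.numeric(raw$value))
    bad <- which(is.na(pos) | is.na(value))
    if (length(bad))
      stop(sprintf("malformed track rows at line(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    tr <- data.frame(pos = pos, value = value)[order(pos), , drop = FALSE]
    if (anyDuplicated(tr$pos))
      stop("duplicate positions in track", call. = FALSE)
  }
  if (any(tr$value < 0))
    stop("occupancy values must be non-negative", call. = FALSE)
  class(tr) <- c("occupancy_track", "data.frame")
  tr
}

## Accept a track data frame or a bare numeric vector of values.
track_values <- function(track) {
  if (is.numeric(track)) return(as.numeric(track))
  if (is.data.frame(track) && "value" %in% names(track))
    return(as.numeric(track$value))
  stop("'track' must be a numeric vector or a data frame with a 'value' column",
       call. = FALSE)
}

with_track_values <- function(track, values) {
  if (is.numeric(track)) return(values)
  track$value <- values
  track
}

#' Rescale an occupancy track to \[0, 1\]
#'
#' Divides the values by the track maximum (default) or by a user-supplied
#' saturation constant, then clips to \[0, 1\]. The result is interpretable
#' as a per-nucleosome probability that a single cell carries the mark.
#'
#' @param track An `occupancy_track` data frame or numeric vector.
#' @param saturation Optional positive constant to divide by instead of the
#'   maximum.
#' @return Same shape as `track`, with values in \[0, 1\].
#' @examples
#' normalize_track(c(2, 4, 8))  # 0.25 0.50 1.00
#' @export
normalize_track <- function(track, saturation = NULL) {
  v <- track_values(track)
  top <- saturation %||% max(v)
  if (!is.numeric(top) || top <= 0)
    stop("track maximum (or 'saturation') must be positive", call. = FALSE)
  with_track_values(track, pmin(pmax(v / top, 0), 1))
}

#' Binarize a track into single-cell-like realizations
#'
#' Population-averaged occupancy is converted into an ensemble of binary
#' sequences: each realization draws position `i` as modified with
#' probability equal to the (normalized) track value, independently across
#' positions and realizations. The ensemble [occupancy_profile()] converges
#' to the track; note the realizations carry no positional correlation
#' beyond the track's own structure.
#'
#' @param track An `occupancy_track` or numeric vector with values in
#'   \[0, 1\].
#' @param n_realizations Number of binary realizations.
#' @param seed Integer seed, or `NULL`.
#' @return A list of binary integer vectors.
#' @export
discretize_track <- function(track, n_realizations, seed = NULL) {
  v <- track_values(track)
  if (any(v < 0 | v > 1))
    stop("track values must lie in [0, 1]; see normalize_track()",
         call. = FALSE)
  stopifnot(n_realizations >= 1)
  with_seed(seed, {
    u <- matrix(stats::runif(n_realizations * length(v)),
                nrow = n_realizations, byrow = TRUE)
    m <- u < matrix(v, nrow = n_realizations, ncol = length(v), byrow = TRUE)
    lapply(seq_len(n_realizations), function(i) as.integer(m[i, ]))
  })
}

#' Estimate chain parameters from an occupancy track
#'
#' Binarizes the track with [discretize_track()] and pools the maximum-
#' likelihood transition estimates across realizations. The recovered
#' `(alpha, beta)` reflect the track's island structure; for the published
#' H3K27me3 data this procedure lands in the threshold-fillable regime.
#'
#' @inheritParams discretize_track
#' @return A fitted [epimarkov()] object.
#' @export
estimate_from_track <- function(track, n_realizations, seed = NULL) {
  estimate_params(discretize_track(track, n_realizations, seed))
}
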