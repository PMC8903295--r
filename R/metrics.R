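#' Bit error rate between mother and reconstruction
#'
#' The per-position mismatch fraction
#' \eqn{\Delta(M, \hat M) = \frac1N \sum_i (m_i - \hat m_i)^2}; for binary
#' sequences this is the squared (equivalently absolute) difference, and
#' for ternary sequences any symbol mismatch counts as one error.
#'
#' @param mother,estimate Integer vectors of equal length (binary or
#'   ternary).
#' @return A number in \[0, 1\].
#' @examples
#' ber(c(1, 0, 1, 0, 1), c(1, 1, 1, 0, 0))  # 0.4
#' @export
ber <- function(mother, estimate) {
  if (length(mother) != length(estimate))
    stop("'mother' and 'estimate' must have equal length", call. = FALSE)
  if (length(mother) == 0L) stop("empty sequences", call. = FALSE)
  mean(mother != estimate)
}

#' Ensemble-averaged reconstruction error
#'
#' Averages [ber()] over paired collections of mothers and estimates and
#' reports the standard error of the mean across pairs.
#'
#' @param mothers,estimates Lists (or row-matrices) of sequences, paired by
#'   index.
#' @param block_sizes Optional integer vector: also report mean
#'   [block_error()] at these block sizes.
#' @return An object of class `"error_report"`: list with `ber` (the mean
#'   \eqn{\bar\Delta}), `n_sequences`, `se`, `per_pair`, and `block_errors`
#'   (named numeric, present when `block_sizes` is given; block size 1
#'   equals `ber`).
#' @export
mean_ensemble_error <- function(mothers, estimates, block_sizes = NULL) {
  mothers <- as_ensemble(mothers)
  estimates <- as_ensemble(estimates)
  if (length(mothers) != length(estimates))
    stop("'mothers' and 'estimates' must be paired collections",
         call. = FALSE)
  per <- mapply(ber, mothers, estimates)
  out <- list(
    ber = mean(per),
    n_sequences = length(per),
    se = if (length(per) > 1L) stats::sd(per) / sqrt(length(per)) else 0,
    per_pair = per
  )
  if (!is.null(block_sizes)) {
    be <- vapply(block_sizes, function(b)
      mean(mapply(function(m, e) block_error(m, e, b), mothers, estimates)),
      numeric(1))
    out$block_errors <- stats::setNames(be, block_sizes)
  }
  class(out) <- "error_report"
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Ensemble reconstruction error over %d pairs\n", x$n_sequences))
  cat(sprintf("  mean BER = %.4f (SE %.4g)\n", x$ber, x$se))
  if (!is.null(x$block_errors)) {
    cat("  mean block error by block size:\n")
    for (b in names(x$block_errors))
      cat(sprintf("    %s: %.4f\n", b, x$block_errors[[b]]))
  }
  invisible(x)
}

#' Block error between mother and reconstruction
#'
#' Partitions positions into consecutive blocks of the given size (the last
#' block may be shorter and is averaged with its true length), computes the
#' absolute difference of the per-block modification densities, and
#' averages over blocks. At block size 1 this reduces exactly to [ber()];
#' larger blocks let opposite-sign errors cancel, so the block error is
#' never larger than the BER.
#'
#' @inheritParams ber
#' @param block Block size (positive integer).
#' @return A number in \[0, 1\].
#' @examples
#' block_error(c(1, 0), c(0, 1), block = 2)  # 0: densities match
#' @export
block_error <- function(mother, estimate, block) {
  if (length(mother) != length(estimate))
    stop("'mother' and 'estimate' must have equal length", call. = FALSE)
  stopifnot(block >= 1)
  idx <- ceiling(seq_along(mother) / block)
  dm <- tapply(mother, idx, mean)
  de <- tapply(estimate, idx, mean)
  mean(abs(dm - de))
}

#' Per-position occupancy profile of an ensemble
#'
#' The population-averaged modification occupancy: the mean of each
#' position across an ensemble of equal-length sequences. For binary
#' ensembles this is the fraction of cells carrying the mark at each
#' nucleosome.
#'
#' @param ensemble A list (or row-matrix) of equal-length sequences.
#' @return Numeric vector of per-position means.
#' @export
occupancy_profile <- function(ensemble) {
  ensemble <- as_ensemble(ensemble)
  len <- unique(lengths(ensemble))
  if (length(len) != 1L)
    stop("all sequences in the ensemble must have equal length",
         call. = FALSE)
  colMeans(do.call(rbind, ensemble))
}
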