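#' Generate a two-modification (ternary) mother sequence
#'
#' Builds a mother carrying two spatially distinct antagonistic marks:
#' a binary chain is generated at `(alpha, beta)` and its state-1 runs are
#' relabelled as modification 1, its state-0 runs as modification 2. With
#' high `alpha` and `beta` this yields long alternating stretches of the
#' two marks with every nucleosome modified — the regime in which an
#' uncorrected daughter at retention 1/2 mismatches about half its
#' positions. Optionally a fraction of positions can be masked to the
#' unmodified state via a second independent chain (`gap_params`), for
#' mothers with genuine unmarked stretches (not the default).
#'
#' @inheritParams generate_mother
#' @param gap_params Optional [epimarkov()] model (or `(alpha, beta)`
#'   pair); where an independent chain drawn from it is 0, the ternary
#'   mother is set to 0.
#' @return Integer vector over \{1, 2\} (or \{0, 1, 2\} with `gap_params`).
#' @export
make_ternary_mother <- function(params, n, seed = NULL, gap_params = NULL) {
  base <- generate_mother(params, n, seed = child_seed(seed, 1L) %||% seed)
  out <- ifelse(base == 1L, 1L, 2L)
  if (!is.null(gap_params)) {
    g <- generate_mother(gap_params, n, seed = child_seed(seed, 2L))
    out[g == 0L] <- 0L
  }
  as.integer(out)
}

#' Generate a bistable ensemble of mother sequences
#'
#' Emulates a parental cell population with two stable epigenetic states:
#' half the mothers are drawn from a high-occupancy chain and half from a
#' low-occupancy chain, producing a bimodal distribution of per-cell mean
#' modification. Replication plus threshold correction should preserve the
#' bimodality.
#'
#' @param n_cells Even number of mothers.
#' @param n Sequence length.
#' @param high_params,low_params [epimarkov()] models (or `(alpha, beta)`
#'   pairs) for the two sub-populations.
#' @param seed Integer seed, or `NULL`.
#' @return A list of `n_cells` binary integer vectors (high-state cells
#'   first).
#' @export
make_bistable_ensemble <- function(n_cells, n, high_params, low_params,
                                   seed = NULL) {
  if (n_cells %% 2 != 0) stop("'n_cells' must be even", call. = FALSE)
  half <- n_cells %/% 2
  c(lapply(seq_len(half), function(i)
      generate_mother(high_params, n, seed = child_seed(seed, i))),
    lapply(seq_len(half), function(i)
      generate_mother(low_params, n, seed = child_seed(seed, half + i))))
}

#' Deterministic island/gap occupancy track
#'
#' A synthetic stand-in for an experimental per-nucleosome occupancy
#' signal: alternating islands of occupancy `high` (length `island_len`)
#' and gaps of occupancy `low` (length `gap_len`), truncated to `n`
#' positions. Useful for exercising the track-discretization arm without
#' external data.
#'
#' @param n Track length.
#' @param island_len,gap_len Island and gap lengths (positive integers).
#' @param high,low Occupancy levels, `high > low >= 0`.
#' @return An `occupancy_track` data frame with columns `pos`, `value`.
#' @export
make_two_level_track <- function(n, island_len, gap_len, high = 0.9,
                                 low = 0.05) {
  stopifnot(n >= 1, island_len >= 1, gap_len >= 1)
  if (!(high > low && low >= 0))
    stop("need high > low >= 0", call. = FALSE)
  unit <- c(rep(high, island_len), rep(low, gap_len))
  tr <- data.frame(pos = seq_len(n),
                   value = rep_len(unit, n))
  class(tr) <- c("occupancy_track", "data.frame")
  tr
}
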