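#' Replicate a mother sequence through the dilution channel
#'
#' DNA replication randomly partitions parental nucleosomes between the two
#' daughter strands: on the tracked daughter each parental nucleosome (and
#' its mark) survives independently with probability `retention` (default
#' 0.5), otherwise it is replaced by a fresh, unmarked nucleosome. The
#' channel is mark-destroying only: \eqn{d_i = m_i z_i} with
#' \eqn{z_i \sim} Bernoulli(`retention`) IID, so \eqn{d_i \le m_i}
#' everywhere. One coin is tossed per nucleosome (the parental tetramer is
#' assumed symmetrically modified).
#'
#' @param mother Binary integer vector.
#' @param retention Survival probability of a parental nucleosome.
#' @param seed Integer seed, or `NULL`.
#' @return Binary integer vector of the same length (the daughter).
#' @examples
#' m <- generate_mother(epimarkov(0.9, 0.9), 50, seed = 1)
#' d <- replicate_chromatin(m, seed = 2)
#' all(d <= m)
#' @export
replicate_chromatin <- function(mother, retention = 0.5, seed = NULL) {
  mother <- assert_binary(mother)
  retention <- assert_prob(retention)
  with_seed(seed, {
    z <- stats::runif(length(mother)) < retention
    as.integer(mother & z)
  })
}

#' Replicate a two-modification (ternary) sequence
#'
#' Same channel for sequences over \{0, 1, 2\} carrying two antagonistic
#' marks: each non-zero symbol survives independently with probability
#' `retention`, otherwise the nucleosome arrives unmarked (0). Zeros are
#' unchanged.
#'
#' @param mother Integer vector over \{0, 1, 2\}.
#' @inheritParams replicate_chromatin
#' @return Ternary integer vector of the same length.
#' @export
replicate_ternary <- function(mother, retention = 0.5, seed = NULL) {
  mother <- assert_ternary(mother)
  retention <- assert_prob(retention)
  with_seed(seed, {
    z <- stats::runif(length(mother)) < retention
    out <- mother
    out[!z] <- 0L
    out
  })
}

#' Iterate replication and correction over several generations
#'
#' Each generation replicates the previous generation's corrected sequence
#' through the dilution channel and applies `corrector` to the result;
#' generation 1 starts from `mother`. Fidelity across generations is judged
#' against the original mother (see [ber()] and [block_error()]).
#'
#' @inheritParams replicate_chromatin
#' @param corrector A function mapping a daughter sequence to a corrected
#'   sequence (e.g. `function(d) threshold_fill(d, 6)` or
#'   `function(d) smap_decode(model, d)`), or `NULL` for no correction.
#' @param generations Number of replication rounds, at least 1.
#' @return A list of length `generations`; element `g` is the corrected
#'   sequence after `g` rounds.
#' @examples
#' m <- generate_mother(epimarkov(0.9, 0.9), 200, seed = 1)
#' gens <- iterate_generations(m, corrector = function(d) threshold_fill(d, 6),
#'                             generations = 3, seed = 2)
#' sapply(gens, ber, mother = m)
#' @export
iterate_generations <- function(mother, retention = 0.5, corrector = NULL,
                                generations = 1, seed = NULL) {
  mother <- assert_binary(mother)
  stopifnot(generations >= 1)
  if (is.null(corrector)) corrector <- identity
  out <- vector("list", generations)
  cur <- mother
  for (g in seq_len(generations)) {
    d <- replicate_chromatin(cur, retention, seed = child_seed(seed, g))
    cur <- assert_binary(corrector(d), arg = "corrector(daughter)")
    out[[g]] <- cur
  }
  out
}
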