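#' Stationary distribution of the modification chain
#'
#' For transition persistence probabilities `alpha` (\eqn{P(1|1)}) and
#' `beta` (\eqn{P(0|0)}) the unique stationary law is
#' \eqn{(P(0), P(1)) = ((1-\alpha), (1-\beta)) / (2-\alpha-\beta)},
#' provided the chain is not the degenerate case \eqn{\alpha=\beta=1} (two
#' absorbing states, no unique stationary law).
#'
#' @param params An [epimarkov()] model or a numeric `(alpha, beta)` pair.
#' @return Numeric vector `c(p0, p1)` summing to 1.
#' @examples
#' stationary_distribution(epimarkov(0.81, 0.815))
#' @export
stationary_distribution <- function(params) {
  p <- as_epimarkov(params)
  if (p$alpha == 1 && p$beta == 1)
    stop(structure(
      class = c("epifill_degenerate_chain", "error", "condition"),
      list(message = "alpha = beta = 1: no unique stationary law",
           call = sys.call(-1))))
  denom <- 2 - p$alpha - p$beta
  c(p0 = (1 - p$alpha) / denom, p1 = (1 - p$beta) / denom)
}

#' Mean contiguous run lengths of the chain
#'
#' Run lengths of each state are geometric, so the mean modified and
#' unmodified island lengths are \eqn{1/(1-\alpha)} and \eqn{1/(1-\beta)}.
#' A persistence probability of 1 yields an infinite mean run (signalled
#' with a classed warning).
#'
#' @inheritParams stationary_distribution
#' @return Numeric vector `c(run1, run0)`.
#' @examples
#' mean_run_lengths(epimarkov(0.9, 0.9))  # c(10, 10)
#' @export
mean_run_lengths <- function(params) {
  p <- as_epimarkov(params)
  if (p$alpha == 1 || p$beta == 1)
    warning(structure(
      class = c("epifill_infinite_run", "warning", "condition"),
      list(message = "persistence probability 1: infinite mean run length",
           call = sys.call(-1))))
  c(run1 = 1 / (1 - p$alpha), run0 = 1 / (1 - p$beta))
}

#' Generate a mother modification sequence
#'
#' Draws a binary sequence of length `n` from the first-order chain: the
#' first nucleosome from the stationary law (uniform in the degenerate
#' \eqn{\alpha=\beta=1} case) and each subsequent one from the transition
#' law given its left neighbour.
#'
#' @inheritParams stationary_distribution
#' @param n Sequence length, at least 1.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Binary integer vector of length `n`.
#' @examples
#' generate_mother(epimarkov(0.9, 0.9), 20, seed = 1)
#' @export
generate_mother <- function(params, n, seed = NULL) {
  p <- as_epimarkov(params)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  stat <- tryCatch(stationary_distribution(p),
                   epifill_degenerate_chain = function(e) c(0.5, 0.5))
  with_seed(seed, {
    u <- stats::runif(n)
    m <- integer(n)
    m[1] <- as.integer(u[1] < stat[2])
    if (n >= 2L) {
      a <- p$alpha; b1 <- 1 - p$beta
      for (i in 2:n)
        m[i] <- if (m[i - 1L] == 1L) as.integer(u[i] < a)
                else as.integer(u[i] < b1)
    }
    m
  })
}

#' Maximum-likelihood estimation of (alpha, beta) from sequences
#'
#' Pools first-order transition counts over one or more binary sequences
#' (transitions never cross sequence boundaries) and returns the transition
#' frequencies \eqn{\hat\alpha = n_{11}/(n_{11}+n_{10})},
#' \eqn{\hat\beta = n_{00}/(n_{00}+n_{01})}. A parameter with no
#' transitions out of its origin state is inestimable and returned as `NA`
#' with a classed warning.
#'
#' @param sequences A binary integer vector or a list of them.
#' @return A fitted [epimarkov()] object carrying the transition `counts`
#'   and binomial standard errors `se`.
#' @examples
#' estimate_params(c(1, 1, 0, 0, 1))  # alpha = beta = 0.5
#' @export
estimate_params <- function(sequences) {
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, assert_binary, arg = "sequences")
  n11 <- n10 <- n00 <- n01 <- 0
  for (x in sequences) {
    if (length(x) < 2L) next
    a <- x[-length(x)]; b <- x[-1L]
    n11 <- n11 + sum(a == 1L & b == 1L)
    n10 <- n10 + sum(a == 1L & b == 0L)
    n00 <- n00 + sum(a == 0L & b == 0L)
    n01 <- n01 + sum(a == 0L & b == 1L)
  }
  from1 <- n11 + n10; from0 <- n00 + n01
  if (from1 == 0)
    warning(structure(
      class = c("epifill_inestimable", "warning", "condition"),
      list(message = "no transitions out of state 1: alpha inestimable",
           call = sys.call(-1))))
  if (from0 == 0)
    warning(structure(
      class = c("epifill_inestimable", "warning", "condition"),
      list(message = "no transitions out of state 0: beta inestimable",
           call = sys.call(-1))))
  alpha <- if (from1 > 0) n11 / from1 else NA_real_
  beta <- if (from0 > 0) n00 / from0 else NA_real_
  se <- c(alpha = if (from1 > 0) sqrt(alpha * (1 - alpha) / from1)
                  else NA_real_,
          beta = if (from0 > 0) sqrt(beta * (1 - beta) / from0)
                 else NA_real_)
  new_epimarkov(alpha, beta,
                counts = c(n11 = n11, n10 = n10, n00 = n00, n01 = n01),
                se = se)
}

#' Observed run lengths of one state, excluding censored boundary runs
#'
#' Helper for relating run-length statistics to the chain parameters: runs
#' touching either end of the sequence are right/left-censored and excluded.
#'
#' @param x Binary integer vector.
#' @param state The state (0 or 1) whose runs are collected.
#' @return Integer vector of complete run lengths (possibly empty).
#' @export
run_lengths <- function(x, state = 1L) {
  x <- assert_binary(x)
  r <- rle(x)
  keep <- r$values == state
  if (length(r$values) >= 1L) {
    keep[1L] <- FALSE
    keep[length(keep)] <- FALSE
  }
  r$lengths[keep]
}
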