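## Sequence-MAP reconstruction of a mother sequence from a daughter.
##
## Because the channel can only destroy marks (P(d=1 | m=0) = 0), every
## observed 1 pins the mother to 1, and the joint maximization of
## P(M | D) = (1/P(D)) prod_i P(m_i | m_{i-1}) P(d_i | m_i)
## factorizes over the maximal runs of zeros flanked by observed ones.
## Each flanked run of k zeros is decoded independently on a two-state
## trellis (Viterbi); unflanked boundary zero-runs are left as zeros (the
## prefix/suffix posterior is not pinned by an observed 1 and is not part of
## the decoding convention).

## Equal log-metrics up to this tolerance are treated as ties; mathematically
## equal path products can differ by float ulps when accumulated in
## different orders (e.g. interior paths (1,0) and (0,1) always tie exactly).
TIE_TOL <- 1e-9

.decode_cache <- new.env(parent = emptyenv())

#' Trellis branch metric
#'
#' The per-transition probability \eqn{P(m_i, d_i \mid m_{i-1}) =
#' P(m_i \mid m_{i-1}) P(d_i \mid m_i)} used on the decoding trellis, with
#' channel law \eqn{P(d=1|m=1) =} `retention`, \eqn{P(d=0|m=1) = 1 -}
#' `retention`, \eqn{P(d=0|m=0) = 1}, \eqn{P(d=1|m=0) = 0}.
#'
#' @inheritParams stationary_distribution
#' @param m_prev,m,d Binary symbols: previous mother state, current mother
#'   state, observed daughter symbol.
#' @param retention Channel retention probability; `NULL` takes it from
#'   `params`.
#' @return A probability.
#' @examples
#' branch_metric(epimarkov(0.9, 0.9), 1, 1, 0)  # 0.9 * 0.5 = 0.45
#' @export
branch_metric <- function(params, m_prev, m, d, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  stopifnot(m_prev %in% 0:1, m %in% 0:1, d %in% 0:1)
  trans <- if (m_prev == 1) (if (m == 1) p$alpha else 1 - p$alpha)
           else (if (m == 0) p$beta else 1 - p$beta)
  chan <- if (m == 1) (if (d == 1) r else 1 - r)
          else (if (d == 0) 1 else 0)
  trans * chan
}

#' Decompose a daughter sequence into decodable segments
#'
#' Finds the maximal runs of zeros flanked by observed ones on both sides —
#' the `(1, 0_k, 1)` sub-sequences on which sequence-MAP decoding operates.
#' Leading and trailing zero-runs have no flanking 1 on one side and are
#' excluded.
#'
#' @param daughter Binary integer vector.
#' @return A data frame with one row per segment: `start` and `end` (1-based
#'   positions of the flanking ones) and `k` (number of interior zeros),
#'   ordered left to right. Zero rows when nothing is decodable.
#' @examples
#' segment_decompose(c(1, 0, 0, 1, 0, 1))  # k = 2 and k = 1
#' @export
segment_decompose <- function(daughter) {
  daughter <- assert_binary(daughter)
  r <- rle(daughter)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values == 0L)
  idx <- idx[idx > 1L & idx < length(r$values)]
  data.frame(start = starts[idx] - 1L, end = ends[idx] + 1L,
             k = r$lengths[idx])
}

## Prefer larger log-score; ties (within TIE_TOL, including -Inf vs -Inf)
## go to the lexicographically smaller path (0 < 1, read from the left).
.pick <- function(sa, pa, sb, pb) {
  if (sa == -Inf && sb == -Inf) tie <- TRUE
  else if (sa > sb + TIE_TOL) return(list(s = sa, p = pa))
  else if (sb > sa + TIE_TOL) return(list(s = sb, p = pb))
  else tie <- TRUE
  d <- which(pa != pb)
  if (length(d) == 0L || pa[d[1L]] < pb[d[1L]]) list(s = max(sa, sb), p = pa)
  else list(s = max(sa, sb), p = pb)
}

#' Decode the interior of a flanked zero-run
#'
#' Exact sequence-MAP decoding of the daughter pattern `(1, 0_k, 1)`:
#' returns the interior mother assignment maximizing the product of branch
#' metrics over all \eqn{2^k} candidate paths, computed by two-state
#' dynamic programming (Viterbi) in O(k). Metrics are accumulated in log
#' space; ties are broken toward the lexicographically smallest path
#' (fewest/earliest-possible zeros). Results are memoized per
#' `(alpha, beta, retention, k)`.
#'
#' @inheritParams branch_metric
#' @param k Number of interior zeros, at least 1.
#' @return Binary integer vector of length `k`: the decoded interior.
#' @examples
#' decode_segment(epimarkov(0.9, 0.9), 3)   # all ones (k <= k* = 6.34)
#' decode_segment(epimarkov(0.9, 0.9), 10)  # all zeros
#' @export
decode_segment <- function(params, k, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  stopifnot(k >= 1)
  k <- as.integer(k)
  key <- sprintf("%.17g|%.17g|%.17g|%d", p$alpha, p$beta, r, k)
  hit <- .decode_cache[[key]]
  if (!is.null(hit)) return(hit)

  ## log branch metrics for interior observations d = 0
  l11 <- log(p$alpha) + log(1 - r)      # 1 -> 1, mark lost in channel
  l10 <- log(1 - p$alpha)               # 1 -> 0 (P(d=0|m=0)=1)
  l00 <- log(p$beta)                    # 0 -> 0
  l01 <- log(1 - p$beta) + log(1 - r)   # 0 -> 1, mark lost

  ## stage 1: from the left flanking 1
  s1 <- l11; p1 <- 1L
  s0 <- l10; p0 <- 0L
  if (k >= 2L) {
    for (j in 2:k) {
      c1 <- .pick(s1 + l11, c(p1, 1L), s0 + l01, c(p0, 1L))
      c0 <- .pick(s1 + l10, c(p1, 0L), s0 + l00, c(p0, 0L))
      s1 <- c1$s; p1 <- c1$p
      s0 <- c0$s; p0 <- c0$p
    }
  }
  ## final transition into the right flanking 1 (d = 1)
  f1 <- s1 + log(p$alpha) + log(r)
  f0 <- s0 + log(1 - p$beta) + log(r)
  best <- .pick(f1, p1, f0, p0)
  out <- best$p
  .decode_cache[[key]] <- out
  out
}

#' Sequence-MAP decoding of a daughter sequence
#'
#' Reconstructs the most probable mother sequence given the daughter:
#' observed ones are kept (the channel cannot create marks), each flanked
#' zero-run is replaced by its [decode_segment()] solution, and unflanked
#' boundary zero-runs are left as zeros. The output maximizes the posterior
#' factorization \eqn{\prod_i P(m_i|m_{i-1}) P(d_i|m_i)} over all mothers
#' consistent with that boundary convention.
#'
#' @inheritParams branch_metric
#' @param daughter Binary integer vector.
#' @return Binary integer vector: the reconstructed mother-like sequence.
#' @examples
#' smap_decode(epimarkov(0.9, 0.9), c(1, 0, 0, 0, 1))  # all ones
#' @export
smap_decode <- function(params, daughter, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  daughter <- assert_binary(daughter)
  segs <- segment_decompose(daughter)
  out <- daughter
  if (nrow(segs) == 0L) return(out)
  for (kk in unique(segs$k)) {
    dec <- decode_segment(p, kk, r)
    for (i in which(segs$k == kk))
      out[(segs$start[i] + 1L):(segs$end[i] - 1L)] <- dec
  }
  out
}

#' Exhaustive-enumeration MAP oracle
#'
#' Validation oracle for [smap_decode()]: enumerates every binary mother of
#' the daughter's length, scores each by the posterior factorization (the
#' stationary law supplies the first-position prior), and returns the
#' maximizer under the same tie-break rule (lexicographically smallest
#' among log-scores tied within tolerance). With
#' `boundary = "convention"` (the default) enumeration is restricted to
#' mothers that are zero on unflanked boundary zero-runs, matching the
#' decoding convention; `boundary = "free"` enumerates all mothers.
#'
#' Refuses sequences longer than 20 positions (combinatorial explosion).
#'
#' @inheritParams smap_decode
#' @param boundary `"convention"` or `"free"` (see Details).
#' @return Binary integer vector: the MAP mother.
#' @export
brute_force_map <- function(params, daughter, retention = NULL,
                            boundary = c("convention", "free")) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  boundary <- match.arg(boundary)
  daughter <- assert_binary(daughter)
  n <- length(daughter)
  if (n > 20L)
    stop("brute_force_map enumerates 2^N mothers; refusing N > 20",
         call. = FALSE)

  ## all mothers as rows, ordered lexicographically (0 < 1, leftmost most
  ## significant) so that which.max ties resolve to the lex-smallest
  idx <- 0:(2^n - 1)
  mat <- vapply(seq_len(n),
                function(j) as.integer(bitwAnd(idx, bitwShiftL(1L, n - j)) > 0),
                integer(length(idx)))
  if (n == 1L) mat <- matrix(mat, ncol = 1L)

  stat <- tryCatch(stationary_distribution(p),
                   epifill_degenerate_chain = function(e) c(0.5, 0.5))
  lmul <- function(w, l) ifelse(w == 0, 0, w * l)  # avoid 0 * -Inf
  score <- lmul(mat[, 1L], log(stat[2])) + lmul(1 - mat[, 1L], log(stat[1]))
  if (n >= 2L) {
    la <- log(p$alpha); l1a <- log(1 - p$alpha)
    lb <- log(p$beta); l1b <- log(1 - p$beta)
    for (j in 2:n) {
      a <- mat[, j - 1L]; b <- mat[, j]
      score <- score + lmul(a * b, la) + lmul(a * (1 - b), l1a) +
        lmul((1 - a) * (1 - b), lb) + lmul((1 - a) * b, l1b)
    }
  }
  ## channel term: feasible iff m >= d elementwise; then
  ## n11 = #ones(d), n10 = #ones(m) - #ones(d)
  ones_m <- rowSums(mat)
  ones_d <- sum(daughter)
  feasible <- !colSums(t(mat) < daughter)
  n10 <- ones_m - ones_d
  score <- score + lmul(rep(ones_d, length(idx)), log(r)) + lmul(n10, log(1 - r))
  score[!feasible] <- -Inf

  if (boundary == "convention") {
    segs <- segment_decompose(daughter)
    free <- rep(FALSE, n)
    if (nrow(segs) > 0L)
      for (i in seq_len(nrow(segs)))
        free[(segs$start[i] + 1L):(segs$end[i] - 1L)] <- TRUE
    pinned0 <- daughter == 0L & !free
    if (any(pinned0))
      score[rowSums(mat[, pinned0, drop = FALSE]) > 0] <- -Inf
  }

  top <- max(score)
  cand <- if (top == -Inf) which(score == -Inf)
          else which(score >= top - TIE_TOL)
  mat[cand[1L], ]
}
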