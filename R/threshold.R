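#' Gap-filling criterion g_k
#'
#' The path-metric difference between the all-ones and all-zeros mother
#' candidates for a daughter segment `(1, 0_k, 1)`:
#' \deqn{g_k(\alpha, \beta) = \tfrac12\left[(\alpha(1-r))^k \alpha -
#'   (1-\alpha)\beta^{k-1}(1-\beta)\right],}
#' which at the biological retention \eqn{r = 1/2} reduces to
#' \eqn{(\alpha/2)^{k+1} - \tfrac12 (1-\alpha)\beta^{k-1}(1-\beta)}.
#' A positive value means sequence-MAP decoding prefers filling the run.
#'
#' @inheritParams branch_metric
#' @param k Gap size (number of interior zeros), at least 1.
#' @return The metric difference (sign is what matters).
#' @examples
#' g_k(epimarkov(0.9, 0.9), 1)  # 0.1975
#' @export
g_k <- function(params, k, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  stopifnot(all(k >= 1))
  0.5 * ((p$alpha * (1 - r))^k * p$alpha -
           (1 - p$alpha) * p$beta^(k - 1) * (1 - p$beta))
}

#' Closed-form root k* of the filling criterion
#'
#' Treating the gap size as real, \eqn{g_k = 0} has the unique root
#' \deqn{k^* = \frac{\log\left[(1-\alpha)(1-\beta) / (\alpha^2 (1-r))\right]}
#'   {\log\left[\alpha(1-r)/\beta\right]} + 1,}
#' which at retention 1/2 is
#' \eqn{\log[(1-\alpha)(1-\beta)/(\alpha^2/2)] / \log[\alpha/(2\beta)] + 1}.
#' Gaps of integer size \eqn{k \le k^*} are filled by sequence-MAP decoding
#' (given \eqn{g_1 > 0}); longer gaps are not.
#'
#' Requires \eqn{0 < \alpha, \beta < 1}, \eqn{g_1 > 0} (otherwise the
#' regime is not threshold-fillable) and \eqn{\alpha(1-r) \ne \beta}
#' (otherwise the log denominator vanishes and there is no finite root —
#' the fill-all boundary).
#'
#' @inheritParams branch_metric
#' @return The real root \eqn{k^*}.
#' @examples
#' k_star(epimarkov(0.9, 0.9))  # about 6.34
#' @export
k_star <- function(params, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  a <- p$alpha; b <- p$beta
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1)
    stop("k_star requires 0 < alpha < 1 and 0 < beta < 1", call. = FALSE)
  if (g_k(p, 1, r) <= 0)
    stop(structure(
      class = c("epifill_not_fillable", "error", "condition"),
      list(message = "g_1 <= 0: region not threshold-fillable",
           call = sys.call(-1))))
  if (a * (1 - r) == b)
    stop(structure(
      class = c("epifill_no_finite_root", "error", "condition"),
      list(message = "alpha (1 - retention) = beta: no finite root (fill-all boundary)",
           call = sys.call(-1))))
  log((1 - a) * (1 - b) / (a^2 * (1 - r))) / log(a * (1 - r) / b) + 1
}

## Largest integer k with g_k > 0 — the "auto" threshold. Equals floor(k*)
## except at integer roots, where equality means the tie-break prefers not
## filling.
auto_threshold <- function(params, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  region <- classify_region(p, r)
  if (region == "a") return(Inf)
  if (region %in% c("c", "d")) return(0L)
  kt <- floor(k_star(p, r))
  while (kt >= 1 && g_k(p, kt, r) <= 0) kt <- kt - 1
  as.integer(kt)
}

#' Classify (alpha, beta) by the optimal filling behaviour
#'
#' Partitions the open unit square of chain parameters by the signs of
#' \eqn{g_1(\alpha, \beta)} and \eqn{\alpha(1-r) - \beta} (at retention
#' 1/2, \eqn{\alpha - 2\beta}):
#' \describe{
#'   \item{a}{\eqn{g_1 > 0}, \eqn{\alpha \ge 2\beta}: every flanked gap is
#'     filled regardless of size (Type-I enzyme; the boundary
#'     \eqn{\alpha = 2\beta} with \eqn{g_1 > 0} has \eqn{g_k > 0} for all
#'     `k` and so belongs here).}
#'   \item{b}{\eqn{g_1 > 0}, \eqn{\alpha < 2\beta}: threshold-k filling
#'     with finite \eqn{k^*} (Type-II enzyme) — the biologically realistic
#'     regime of long modified and unmodified islands.}
#'   \item{c}{\eqn{g_1 \le 0}, \eqn{\alpha \le 2\beta}: nothing is filled
#'     (small alpha).}
#'   \item{d}{\eqn{g_1 \le 0}, \eqn{\alpha > 2\beta}: intermediate filling;
#'     decode with [smap_decode()] rather than a threshold rule.}
#' }
#' Boundary curves are assigned to the non-filling side (g_1 = 0 counts as
#' not fillable).
#'
#' @inheritParams branch_metric
#' @return A single character: `"a"`, `"b"`, `"c"` or `"d"`.
#' @examples
#' classify_region(epimarkov(0.9, 0.1))  # "a"
#' classify_region(epimarkov(0.9, 0.9))  # "b"
#' @export
classify_region <- function(params, retention = NULL) {
  p <- as_epimarkov(params)
  r <- assert_prob(retention %||% p$retention, "retention")
  a <- p$alpha; b <- p$beta
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1)
    stop("classify_region requires 0 < alpha < 1 and 0 < beta < 1",
         call. = FALSE)
  g1 <- g_k(p, 1, r)
  steep <- a * (1 - r) > b   # alpha > 2 beta at retention 1/2
  flat <- a * (1 - r) == b
  if (g1 > 0) {
    if (steep || flat) "a" else "b"
  } else {
    if (steep) "d" else "c"
  }
}

#' Threshold-k gap filling
#'
#' The enzyme-implementable decoder: every run of zeros of length
#' `k <= k_t` flanked by ones on both sides is filled with ones; all other
#' positions (including unflanked boundary zero-runs) are unchanged. With
#' `k_t = 0` nothing is filled; `k_t = Inf` fills every flanked gap
#' ([fill_all()]). Idempotent.
#'
#' @param daughter Binary integer vector.
#' @param k_t Non-negative integer threshold (or `Inf`).
#' @return Binary integer vector.
#' @examples
#' threshold_fill(c(1, 0, 0, 1, 0, 0, 0, 1), k_t = 2)
#' @export
threshold_fill <- function(daughter, k_t) {
  daughter <- assert_binary(daughter)
  if (!is.numeric(k_t) || length(k_t) != 1L || is.na(k_t) || k_t < 0)
    stop("'k_t' must be a non-negative integer (or Inf)", call. = FALSE)
  if (k_t == 0) return(daughter)
  segs <- segment_decompose(daughter)
  out <- daughter
  for (i in which(segs$k <= k_t))
    out[(segs$start[i] + 1L):(segs$end[i] - 1L)] <- 1L
  out
}

#' Fill every flanked unmodified run
#'
#' The Type-I enzyme rule: all zeros between two ones become ones,
#' regardless of run length. Equivalent to `threshold_fill(daughter, Inf)`.
#'
#' @param daughter Binary integer vector.
#' @return Binary integer vector.
#' @export
fill_all <- function(daughter) {
  threshold_fill(daughter, Inf)
}

#' Threshold filling for two antagonistic modifications
#'
#' Applies the threshold rule separately per modification on a ternary
#' daughter: a zero-run of length at most `k_t` flanked on both sides by
#' modification `v` (1 or 2) is filled with `v`. Runs flanked by discordant
#' marks are never filled. Both enzymes read the original daughter, so the
#' result does not depend on which modification is corrected first, and no
#' position can receive conflicting fills.
#'
#' @param daughter Integer vector over \{0, 1, 2\}.
#' @param k_t Non-negative integer threshold (or `Inf`).
#' @return Ternary integer vector.
#' @examples
#' antagonistic_fill(c(1, 0, 0, 1, 2, 0, 2), k_t = 2)
#' @export
antagonistic_fill <- function(daughter, k_t) {
  daughter <- assert_ternary(daughter)
  if (!is.numeric(k_t) || length(k_t) != 1L || is.na(k_t) || k_t < 0)
    stop("'k_t' must be a non-negative integer (or Inf)", call. = FALSE)
  if (k_t == 0) return(daughter)
  r <- rle(daughter)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- daughter
  idx <- which(r$values == 0L)
  idx <- idx[idx > 1L & idx < length(r$values)]
  for (i in idx) {
    v <- r$values[i - 1L]
    if (v != 0L && r$values[i + 1L] == v && r$lengths[i] <= k_t)
      out[starts[i]:ends[i]] <- v
  }
  out
}
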