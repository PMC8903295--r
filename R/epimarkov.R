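#' Two-state Markov model of a histone modification pattern
#'
#' Constructs (or fits) the first-order Markov chain used throughout the
#' package to describe the presence/absence pattern of one histone mark along
#' a chromatin region. The chain has two parameters: `alpha`, the probability
#' that a modified nucleosome is followed by a modified one
#' (\eqn{P(m_i = 1 \mid m_{i-1} = 1)}), and `beta`, the probability that an
#' unmodified nucleosome is followed by an unmodified one
#' (\eqn{P(m_i = 0 \mid m_{i-1} = 0)}). High `alpha` and `beta` produce the
#' biologically common picture of long modified islands separated by long
#' unmodified gaps: mean run lengths are \eqn{1/(1-\alpha)} and
#' \eqn{1/(1-\beta)}.
#'
#' When `data` is supplied the parameters are estimated by maximum likelihood
#' from the observed transition counts (see [estimate_params()]); otherwise
#' `alpha` and `beta` are taken as given.
#'
#' @param alpha Probability of a 1 following a 1.
#' @param beta Probability of a 0 following a 0.
#' @param data Optional list of binary integer vectors (or a single vector);
#'   if given, `alpha` and `beta` are estimated from it and must not be set.
#' @param retention Per-nucleosome probability that a parental nucleosome
#'   (and its mark) lands on the tracked daughter strand at replication.
#'   The biological default is 0.5 (random segregation of parental
#'   tetramers).
#' @return An object of class `"epimarkov"`: a list with elements `alpha`,
#'   `beta`, `retention`, and, when fitted, `counts` (named transition
#'   counts `n11`, `n10`, `n00`, `n01`) and `se` (binomial standard errors
#'   of the estimates).
#' @seealso [simulate.epimarkov()] to draw mother sequences,
#'   [predict.epimarkov()] to reconstruct a mother from a daughter,
#'   [k_star()] and [classify_region()] for the decoding-regime geometry.
#' @examples
#' m <- epimarkov(alpha = 0.9, beta = 0.9)
#' summary(m)
#' moms <- simulate(m, nsim = 5, n = 200, seed = 1)
#' fit <- epimarkov(data = moms)
#' coef(fit)
#' @export
epimarkov <- function(alpha = NULL, beta = NULL, data = NULL, retention = 0.5) {
  retention <- assert_prob(retention)
  if (!is.null(data)) {
    if (!is.null(alpha) || !is.null(beta))
      stop("give either (alpha, beta) or 'data', not both", call. = FALSE)
    obj <- estimate_params(data)
    obj$retention <- retention
    return(obj)
  }
  alpha <- assert_prob(alpha)
  beta <- assert_prob(beta)
  new_epimarkov(alpha, beta, retention)
}

new_epimarkov <- function(alpha, beta, retention = 0.5, counts = NULL,
                          se = NULL) {
  structure(
    list(alpha = alpha, beta = beta, retention = retention,
         counts = counts, se = se),
    class = "epimarkov"
  )
}

## Coerce (alpha, beta) vectors or epimarkov objects to the model class.
as_epimarkov <- function(x, retention = 0.5) {
  if (inherits(x, "epimarkov")) return(x)
  if (is.numeric(x) && length(x) == 2L)
    return(new_epimarkov(assert_prob(x[[1]], "alpha"),
                         assert_prob(x[[2]], "beta"), retention))
  stop("'params' must be an epimarkov object or a numeric (alpha, beta) pair",
       call. = FALSE)
}

#' @export
print.epimarkov <- function(x, ...) {
  cat("Two-state Markov chain for a histone modification pattern\n")
  cat(sprintf("  alpha = P(1|1) = %s\n", format(x$alpha)))
  cat(sprintf("  beta  = P(0|0) = %s\n", format(x$beta)))
  cat(sprintf("  replication retention = %s\n", format(x$retention)))
  if (!is.null(x$counts))
    cat(sprintf("  fitted from %d transitions\n", sum(x$counts)))
  invisible(x)
}

#' @export
coef.epimarkov <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Summarize a fitted or specified modification chain
#'
#' Reports the stationary law, mean run lengths, the decoding-regime region
#' label and (where defined) the optimal filling threshold.
#'
#' @param object An [epimarkov()] model.
#' @param ... Unused.
#' @return An object of class `"summary.epimarkov"`.
#' @export
summary.epimarkov <- function(object, ...) {
  a <- object$alpha; b <- object$beta
  interior <- a > 0 && a < 1 && b > 0 && b < 1
  stat <- tryCatch(stationary_distribution(object),
                   epifill_degenerate_chain = function(e) c(0.5, 0.5))
  runs <- if (a < 1 && b < 1) mean_run_lengths(object) else c(Inf, Inf)
  region <- if (interior) classify_region(object) else NA_character_
  ks <- if (interior && g_k(object, 1) > 0 && a < 2 * b)
    k_star(object) else NA_real_
  out <- list(model = object, stationary = stat, run_lengths = runs,
              region = region, k_star = ks,
              k_auto = if (interior) tryCatch(auto_threshold(object),
                                              error = function(e) NA_integer_)
                       else NA_integer_)
  class(out) <- "summary.epimarkov"
  out
}

#' @export
print.summary.epimarkov <- function(x, ...) {
  print(x$model)
  cat(sprintf("  stationary P(modified) = %.4f\n", x$stationary[2]))
  cat(sprintf("  mean run lengths: modified %.2f, unmodified %.2f\n",
              x$run_lengths[1], x$run_lengths[2]))
  if (!is.na(x$region))
    cat(sprintf("  parameter region: %s\n", x$region))
  if (!is.na(x$k_star))
    cat(sprintf("  k* = %.3f (threshold filling optimal at k_t = %d)\n",
                x$k_star, x$k_auto))
  else if (!is.na(x$region) && x$region == "a")
    cat("  fill-all regime: every flanked gap should be filled\n")
  else if (!is.na(x$region))
    cat("  filling not beneficial in this regime\n")
  invisible(x)
}

#' Simulate mother modification sequences from the chain
#'
#' Draws `nsim` independent mother sequences of length `n` from the model,
#' each from its own deterministic child stream so that ensembles are
#' reproducible element-wise.
#'
#' @param object An [epimarkov()] model.
#' @param nsim Number of sequences.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param n Sequence length (number of nucleosomes).
#' @param ... Unused.
#' @return A list of `nsim` binary integer vectors.
#' @export
simulate.epimarkov <- function(object, nsim = 1, seed = NULL, n = 1000, ...) {
  stopifnot(nsim >= 1)
  out <- vector("list", nsim)
  for (i in seq_len(nsim))
    out[[i]] <- generate_mother(object, n, seed = child_seed(seed, i))
  if (is.null(seed)) out else structure(out, seed = seed)
}

#' Reconstruct a mother-like sequence from a daughter
#'
#' Applies one of the package's decoders to a replicated daughter sequence:
#' exact sequence-MAP trellis decoding (`"smap"`), the threshold-k filling
#' rule (`"threshold"`), unconditional gap filling (`"fill_all"`), or no
#' correction (`"none"`).
#'
#' @param object An [epimarkov()] model (supplies `alpha`, `beta` and the
#'   channel retention).
#' @param daughter A binary integer vector, or a list of them.
#' @param method Decoder to use.
#' @param k_t Threshold for `method = "threshold"`: `"auto"` (the largest
#'   integer `k` with `g_k > 0`, i.e. `floor(k_star)` away from integer
#'   roots) or a non-negative integer.
#' @param ... Unused.
#' @return The reconstructed sequence (or list of them).
#' @export
predict.epimarkov <- function(object, daughter,
                              method = c("smap", "threshold", "fill_all",
                                         "none"),
                              k_t = "auto", ...) {
  method <- match.arg(method)
  if (is.list(daughter))
    return(lapply(daughter, function(d)
      predict(object, d, method = method, k_t = k_t)))
  switch(method,
    smap = smap_decode(object, daughter),
    threshold = {
      kt <- if (identical(k_t, "auto")) auto_threshold(object)
            else as.integer(k_t)
      threshold_fill(daughter, kt)
    },
    fill_all = fill_all(daughter),
    none = assert_binary(daughter)
  )
}

#' Plot the gap-filling criterion of a modification chain
#'
#' Draws \eqn{g_k(\alpha, \beta)} against the gap size `k`, with the sign
#' change (the root \eqn{k^*}) marked where it exists. Positive values mean
#' sequence-MAP decoding fills a flanked unmodified run of that length.
#'
#' @param x An [epimarkov()] model.
#' @param k_max Largest gap size shown.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of (k, g_k) values plotted.
#' @export
plot.epimarkov <- function(x, k_max = 15, ...) {
  k <- seq_len(k_max)
  g <- vapply(k, function(kk) g_k(x, kk), numeric(1))
  graphics::plot(k, g, type = "b", pch = 16,
                 xlab = "gap size k (nucleosomes)",
                 ylab = expression(g[k](alpha, beta)), ...)
  graphics::abline(h = 0, lty = 2)
  ks <- tryCatch(k_star(x), error = function(e) NA_real_)
  if (is.finite(ks)) {
    graphics::abline(v = ks, col = "grey40", lty = 3)
    graphics::mtext(sprintf("k* = %.2f", ks), side = 3, adj = 1, cex = 0.8)
  }
  invisible(data.frame(k = k, g_k = g))
}
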