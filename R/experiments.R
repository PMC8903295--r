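## End-to-end computational experiments: parameter-grid error heatmaps,
## threshold sweeps, the track pipeline, multi-generation propagation and the
## antagonistic two-modification run. Each is re-runnable bit-identically
## from its arguments plus a seed; TSV outputs carry a header row.

## Shared inner loop: ensemble-mean reconstruction error at one (alpha, beta).
ensemble_error <- function(model, n_mothers, n_daughters, n, decoder, seed) {
  per <- numeric(n_mothers * n_daughters)
  idx <- 0L
  for (i in seq_len(n_mothers)) {
    m <- generate_mother(model, n, seed = child_seed(seed, i))
    dseed <- child_seed(seed, n_mothers + i)
    ds <- with_seed(dseed, lapply(seq_len(n_daughters), function(j)
      replicate_chromatin(m, model$retention)))
    for (d in ds) {
      idx <- idx + 1L
      per[idx] <- ber(m, decoder(d))
    }
  }
  c(mean_error = mean(per), se = stats::sd(per) / sqrt(length(per)))
}

#' Reconstruction-error heatmap over the (alpha, beta) grid
#'
#' For each grid point: generate mothers, replicate each through the
#' dilution channel, decode every daughter with sequence-MAP, and average
#' the bit error against the mother. Default sizes are scaled down for a
#' desk run; `full = TRUE` restores the 300 mothers x 200 daughters
#' ensemble.
#'
#' @param alphas,betas Grid values in (0, 1).
#' @param n_mothers,n_daughters Ensemble sizes (daughters per mother).
#' @param n Sequence length.
#' @param retention Channel retention probability.
#' @param seed Integer seed.
#' @param out Optional TSV path for the result table.
#' @param full Use the full-scale ensemble sizes (300 x 200).
#' @param verbose Print one progress line per grid point.
#' @return Data frame with columns `alpha`, `beta`, `mean_error`, `se`.
#' @export
run_heatmap <- function(alphas = seq(0.05, 0.95, by = 0.05),
                        betas = seq(0.05, 0.95, by = 0.05),
                        n_mothers = 30, n_daughters = 20, n = 1000,
                        retention = 0.5, seed = 1, out = NULL,
                        full = FALSE, verbose = FALSE) {
  if (full) { n_mothers <- 300; n_daughters <- 200 }
  grid <- expand.grid(alpha = alphas, beta = betas)
  res <- matrix(NA_real_, nrow(grid), 2)
  for (g in seq_len(nrow(grid))) {
    model <- epimarkov(grid$alpha[g], grid$beta[g], retention = retention)
    t0 <- proc.time()[["elapsed"]]
    res[g, ] <- ensemble_error(model, n_mothers, n_daughters, n,
                               function(d) smap_decode(model, d),
                               seed = child_seed(seed, g))
    if (verbose)
      message(sprintf(
        "heatmap alpha=%.3f beta=%.3f n=%d elapsed=%.2fs mean=%.4f se=%.4g",
        grid$alpha[g], grid$beta[g], n_mothers * n_daughters,
        proc.time()[["elapsed"]] - t0, res[g, 1], res[g, 2]))
  }
  tab <- cbind(grid, mean_error = res[, 1], se = res[, 2])
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

#' Mean error against the filling threshold
#'
#' Sweeps the threshold-k filling rule over `k_t` values (0 = fill
#' nothing) at fixed `(alpha, beta)`, using the same daughters at every
#' threshold so the curve is paired. For threshold-fillable (region b)
#' parameters the curve is non-monotone with its minimum at the integer
#' optimum implied by `k_star`.
#'
#' @inheritParams run_heatmap
#' @param alpha,beta Chain parameters.
#' @param k_t_values Thresholds to sweep.
#' @return Data frame with columns `alpha`, `beta`, `k_t`, `mean_error`,
#'   `se`, with attributes `argmin` (the minimizing `k_t`) and `k_auto`
#'   (the model-implied threshold, `NA` outside the fillable regime).
#' @export
run_threshold_sweep <- function(alpha, beta, k_t_values = 0:12,
                                n_mothers = 30, n_daughters = 20, n = 1000,
                                retention = 0.5, seed = 1, out = NULL,
                                full = FALSE) {
  if (full) { n_mothers <- 300; n_daughters <- 200 }
  model <- epimarkov(alpha, beta, retention = retention)
  sums <- matrix(0, length(k_t_values), 2)  # running sum, sum of squares
  npairs <- n_mothers * n_daughters
  for (i in seq_len(n_mothers)) {
    m <- generate_mother(model, n, seed = child_seed(seed, i))
    ds <- with_seed(child_seed(seed, n_mothers + i),
                    lapply(seq_len(n_daughters), function(j)
                      replicate_chromatin(m, retention)))
    for (d in ds) {
      e <- vapply(k_t_values, function(kt) ber(m, threshold_fill(d, kt)),
                  numeric(1))
      sums[, 1] <- sums[, 1] + e
      sums[, 2] <- sums[, 2] + e^2
    }
  }
  me <- sums[, 1] / npairs
  se <- sqrt(pmax(sums[, 2] / npairs - me^2, 0) / npairs)
  tab <- data.frame(alpha = alpha, beta = beta, k_t = k_t_values,
                    mean_error = me, se = se)
  attr(tab, "argmin") <- k_t_values[which.min(me)]
  attr(tab, "k_auto") <- tryCatch(auto_threshold(model),
                                  error = function(e) NA)
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

#' Track pipeline: binarize, replicate, correct, score
#'
#' The experimental-data arm: normalize an occupancy track, draw
#' single-cell-like binary mothers from it, replicate each through the
#' channel, apply threshold filling at each `k_t`, and report the mean
#' error plus the corrected-daughter occupancy profile per threshold.
#'
#' @inheritParams run_threshold_sweep
#' @param track An `occupancy_track`, numeric vector, or path to a track
#'   file (read with [read_track()]).
#' @param n_mothers Binary realizations of the track.
#' @param n_daughters Daughters per realization.
#' @return List with `errors` (data frame `k_t`, `mean_error`, `se`),
#'   `profiles` (matrix, one row per `k_t`, of corrected-daughter
#'   occupancy), and `mother_profile` (the normalized track values).
#' @export
run_track_pipeline <- function(track, k_t_values = 0:10, n_mothers = 100,
                               n_daughters = 100, retention = 0.5, seed = 1,
                               out = NULL) {
  if (is.character(track)) track <- read_track(track)
  track <- normalize_track(track)
  v <- track_values(track)
  mothers <- discretize_track(track, n_mothers, seed = child_seed(seed, 1L))
  nk <- length(k_t_values)
  sums <- matrix(0, nk, 2)
  occ <- matrix(0, nk, length(v))
  npairs <- n_mothers * n_daughters
  for (i in seq_len(n_mothers)) {
    m <- mothers[[i]]
    ds <- with_seed(child_seed(seed, 1L + i),
                    lapply(seq_len(n_daughters), function(j)
                      replicate_chromatin(m, retention)))
    for (d in ds) {
      for (ki in seq_len(nk)) {
        corr <- threshold_fill(d, k_t_values[ki])
        e <- ber(m, corr)
        sums[ki, 1] <- sums[ki, 1] + e
        sums[ki, 2] <- sums[ki, 2] + e^2
        occ[ki, ] <- occ[ki, ] + corr
      }
    }
  }
  me <- sums[, 1] / npairs
  se <- sqrt(pmax(sums[, 2] / npairs - me^2, 0) / npairs)
  errors <- data.frame(k_t = k_t_values, mean_error = me, se = se)
  if (!is.null(out))
    utils::write.table(errors, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(errors = errors, profiles = occ / npairs, mother_profile = v)
}

#' Error propagation across replication generations
#'
#' Repeats replicate-then-correct for several generations (each
#' generation's parent is the previous corrected output) over an ensemble
#' of mothers and reports mean block errors against the original mothers.
#'
#' @inheritParams run_threshold_sweep
#' @param corrector `"threshold"`, `"smap"`, `"fill_all"` or `"none"`.
#' @param k_t Threshold for `corrector = "threshold"` (`"auto"` or an
#'   integer).
#' @param generations Number of replication rounds.
#' @param block_sizes Block sizes for [block_error()] (size 1 is the BER).
#' @param n_mothers Ensemble size.
#' @return Data frame with columns `generation`, `block_size`,
#'   `mean_error`.
#' @export
run_multigeneration <- function(alpha, beta,
                                corrector = c("threshold", "smap",
                                              "fill_all", "none"),
                                k_t = "auto", generations = 5,
                                block_sizes = c(1, 5, 10, 25),
                                n_mothers = 30, n = 1000, retention = 0.5,
                                seed = 1, out = NULL) {
  corrector <- match.arg(corrector)
  model <- epimarkov(alpha, beta, retention = retention)
  corr_fun <- switch(corrector,
    threshold = {
      kt <- if (identical(k_t, "auto")) auto_threshold(model)
            else as.numeric(k_t)
      function(d) threshold_fill(d, kt)
    },
    smap = function(d) smap_decode(model, d),
    fill_all = fill_all,
    none = NULL
  )
  acc <- matrix(0, generations, length(block_sizes))
  for (i in seq_len(n_mothers)) {
    m <- generate_mother(model, n, seed = child_seed(seed, i))
    gens <- iterate_generations(m, retention, corr_fun, generations,
                                seed = child_seed(seed, n_mothers + i))
    for (g in seq_len(generations))
      acc[g, ] <- acc[g, ] + vapply(block_sizes, function(b)
        block_error(m, gens[[g]], b), numeric(1))
  }
  tab <- data.frame(
    generation = rep(seq_len(generations), times = length(block_sizes)),
    block_size = rep(block_sizes, each = generations),
    mean_error = as.vector(acc / n_mothers)
  )
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

#' Antagonistic two-modification experiment
#'
#' Builds a fully two-mark-covered ternary mother (long alternating
#' stretches of modifications 1 and 2), replicates it, corrects each
#' daughter with per-modification threshold filling, and reports the
#' symbol-mismatch error before and after correction.
#'
#' @inheritParams run_threshold_sweep
#' @param n Sequence length (500 nucleosomes by default).
#' @param k_t Per-modification filling threshold.
#' @param n_daughters Number of replicate daughters.
#' @return List with `uncorrected` and `corrected` (both
#'   `"error_report"`), and `example` (mother, one daughter and its
#'   correction, for display).
#' @export
run_antagonistic <- function(alpha = 0.9, beta = 0.9, n = 500, k_t = 6,
                             n_daughters = 200, retention = 0.5, seed = 1) {
  mother <- make_ternary_mother(epimarkov(alpha, beta), n, seed = seed)
  daughters <- lapply(seq_len(n_daughters), function(j)
    replicate_ternary(mother, retention, seed = child_seed(seed, j + 1L)))
  corrected <- lapply(daughters, antagonistic_fill, k_t = k_t)
  mothers <- rep(list(mother), n_daughters)
  list(
    uncorrected = mean_ensemble_error(mothers, daughters),
    corrected = mean_ensemble_error(mothers, corrected),
    example = list(mother = mother, daughter = daughters[[1]],
                   corrected = corrected[[1]])
  )
}
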