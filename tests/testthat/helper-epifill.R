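## Shared helpers: independent oracles and small generators. These recompute
## probabilities from first principles (no package internals) so that tests
## check the implementation against a second route.

## Transition probability P(m | m_prev) written out directly.
oracle_trans <- function(alpha, beta, m_prev, m) {
  if (m_prev == 1) { if (m == 1) alpha else 1 - alpha }
  else { if (m == 0) beta else 1 - beta }
}

## Channel probability P(d | m): marks are lost with prob 1 - r, never made.
oracle_chan <- function(r, m, d) {
  if (m == 1) { if (d == 1) r else 1 - r }
  else { if (d == 0) 1 else 0 }
}

## Exhaustive MAP over the 2^k interior assignments of (1, 0_k, 1),
## enumerated in lexicographic order (0 < 1 from the left) and keeping the
## first metric within tie tolerance of the maximum.
oracle_segment <- function(alpha, beta, r, k, tol = 1e-9) {
  paths <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  paths <- paths[do.call(order, as.data.frame(paths)), , drop = FALSE]
  score <- apply(paths, 1, function(p) {
    full <- c(1L, p, 1L)
    d <- c(1L, rep(0L, k), 1L)
    s <- 0
    for (i in 2:length(full))
      s <- s + log(oracle_trans(alpha, beta, full[i - 1], full[i])) +
        log(oracle_chan(r, full[i], d[i]))
    s
  })
  as.integer(paths[which(score >= max(score) - tol)[1], ])
}

## All binary vectors of length n, ordered lexicographically.
all_binary <- function(n) {
  idx <- 0:(2^n - 1)
  m <- vapply(seq_len(n),
              function(j) as.integer(bitwAnd(idx, bitwShiftL(1L, n - j)) > 0),
              integer(length(idx)))
  if (n == 1L) m <- matrix(m, ncol = 1L)
  m
}

## Power-iterate the 2x2 transition matrix to its fixed point: an
## independent route to the stationary law.
oracle_stationary <- function(alpha, beta, iters = 10000) {
  P <- rbind(c(beta, 1 - beta), c(1 - alpha, alpha))
  v <- c(0.5, 0.5)
  for (i in seq_len(iters)) v <- as.vector(v %*% P)
  v
}

random_region_b <- function() {
  repeat {
    a <- runif(1, 0.55, 0.99)
    b <- runif(1, 0.55, 0.99)
    m <- epimarkov(a, b)
    if (a < 2 * b && g_k(m, 1) > 0 && abs(a - 2 * b) > 1e-3) return(m)
  }
}
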