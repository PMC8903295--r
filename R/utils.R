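`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `code` under a temporary RNG state seeded with `seed`; restore the
## caller's stream afterwards so seeded calls never perturb a surrounding
## simulation. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic child stream per ensemble index: element i of an ensemble is
## reproducible on its own, independent of how many elements precede it.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483647 * 48271 + i) %% 2147483647)
}

assert_binary <- function(x, arg = deparse(substitute(x))) {
  if (length(x) < 1L)
    stop(sprintf("'%s' must be a non-empty sequence", arg), call. = FALSE)
  if (anyNA(x) || !all(x == 0L | x == 1L))
    stop(sprintf("'%s' must contain only 0/1 values", arg), call. = FALSE)
  as.integer(x)
}

assert_ternary <- function(x, arg = deparse(substitute(x))) {
  if (length(x) < 1L)
    stop(sprintf("'%s' must be a non-empty sequence", arg), call. = FALSE)
  if (anyNA(x) || !all(x %in% c(0L, 1L, 2L)))
    stop(sprintf("'%s' must contain only 0/1/2 values", arg), call. = FALSE)
  as.integer(x)
}

assert_prob <- function(p, arg = deparse(substitute(p))) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", arg), call. = FALSE)
  as.numeric(p)
}

## Ensembles travel as lists of integer vectors; accept a matrix (rows =
## sequences) for convenience.
as_ensemble <- function(x) {
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  if (!is.list(x) || length(x) == 0L)
    stop("expected a non-empty list of sequences", call. = FALSE)
  x
}
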