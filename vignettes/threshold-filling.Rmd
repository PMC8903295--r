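---
title: "Threshold filling as MAP decoding of histone-mark inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold filling as MAP decoding of histone-mark inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifill)
```

## The inheritance problem as a communication channel

During DNA replication each daughter strand receives only about half of the
parental nucleosomes, and with them only about half of the parental histone
marks; the other nucleosomes arrive fresh and unmarked. Yet repressive
domains (H3K27me3, H3K9me3) are re-established with high fidelity within a
cell cycle. `epifill` treats this as a decoding problem: the parental
pattern is a transmitted message, replication is a noisy channel that can
erase marks but never create them, and the mark-writing enzymes are the
decoder.

Three ingredients define the model.

**The mother chain.** The presence/absence pattern of one mark along `N`
nucleosomes, $M = (m_1, \dots, m_N)$ with $m_i \in \{0, 1\}$, is a
first-order homogeneous Markov chain with two persistence parameters:
$\alpha = P(m_i = 1 \mid m_{i-1} = 1)$ and
$\beta = P(m_i = 0 \mid m_{i-1} = 0)$. Mean modified and unmodified island
lengths are $1/(1-\alpha)$ and $1/(1-\beta)$ nucleosomes, so chromatin-like
patterns — long marked domains separated by long unmarked gaps — live at
$\alpha, \beta$ close to 1. The first nucleosome is drawn from the
stationary law $((1-\alpha), (1-\beta))/(2-\alpha-\beta)$; the source
leaves the initial law open, and stationarity is the one choice that makes
every position statistically equivalent under the homogeneous-chain
framing. (In the degenerate corner $\alpha = \beta = 1$ there is no unique
stationary law and the generator falls back to a fair coin for $m_1$.)

**The dilution channel.** The tracked daughter is $d_i = m_i z_i$ with
$z_i \sim \mathrm{Bernoulli}(r)$ IID and retention $r = 1/2$ by default
(random segregation of parental tetramers, assumed symmetrically modified,
hence one coin per nucleosome rather than per histone copy). `retention`
is exposed as a parameter so that unequal strand partitioning can be
explored, but every default in the package is the biological 1/2.

**The decoder.** The sequence-MAP estimate maximizes
$P(M \mid D) \propto \prod_i P(m_i \mid m_{i-1})\, P(d_i \mid m_i)$.
Because $P(d = 1 \mid m = 0) = 0$, every observed 1 pins the mother, and
the maximization factorizes over maximal zero-runs flanked by observed
ones. Each flanked run $(1, 0_k, 1)$ is decoded on a two-state trellis by
the Viterbi algorithm in $O(k)$; `smap_decode()` is exact, and
`brute_force_map()` re-derives the same answer by enumerating all $2^N$
mothers on short inputs — the two routes are compared exhaustively in the
test suite.

## From trellis decoding to a rule enzymes could execute

For a flanked zero-run of length $k$ the competition is effectively
between the all-ones and all-zeros interior paths, with metric difference

$$g_k(\alpha, \beta) \;=\; \left(\tfrac{\alpha}{2}\right)^{k+1}
 - \tfrac12 (1-\alpha)\, \beta^{k-1} (1-\beta)$$

at retention $1/2$ (the package implements the general-$r$ form, which
reduces to this printed one). Treating $k$ as real, $g_k = 0$ has the
unique root

$$k^* \;=\; \frac{\log\!\big[(1-\alpha)(1-\beta)\,/\,(\alpha^2/2)\big]}
 {\log\!\big[\alpha / (2\beta)\big]} + 1 ,$$

and `k_star()` cross-validates this closed form against a numeric root
of $g_k$ to $10^{-9}$. The $(\alpha, \beta)$ unit square then splits into
four regimes (`classify_region()`):

* **a** ($g_1 > 0$, $\alpha \ge 2\beta$): every flanked gap should be
  filled, whatever its size — a "Type-I" enzyme that joins any two marks it
  can see.
* **b** ($g_1 > 0$, $\alpha < 2\beta$): fill gaps of size at most
  $\lfloor k^* \rfloor$, leave longer gaps alone — the **threshold-k
  filling** rule of a "Type-II" enzyme. This is the biologically realistic
  regime of long islands of both states.
* **c** ($g_1 \le 0$, $\alpha \le 2\beta$): filling never helps.
* **d** ($g_1 \le 0$, $\alpha > 2\beta$): intermediate filling; no simple
  threshold rule exists and the package exposes this regime through
  `smap_decode()` only.

Boundary curves are assigned to the non-filling side, except
$\alpha = 2\beta$ with $g_1 > 0$, where $g_k > 0$ for every $k$ and the
point behaves (and is classified) as fill-all. The central result — proved
here empirically rather than assumed — is that in region b
`threshold_fill(d, floor(k_star(m)))` and `smap_decode(m, d)` agree on
*every* daughter; the tests assert this exhaustively on short sequences
and on $10^4$ random length-500 daughters at $\alpha = \beta = 0.9$
($k^* \approx 6.34$, threshold 6).

The "auto" threshold used by `predict(..., method = "threshold")` is the
largest integer $k$ with $g_k > 0$. This equals $\lfloor k^* \rfloor$
except in the measure-zero case of an integer root, where $g_{k^*} = 0$
and the decoder's tie-break (below) prefers not filling.

## Numerical choices

* **Log-space metrics.** Path metrics are products of up to thousands of
  probabilities; all comparisons happen on sums of logs.
* **Ties.** Two candidate paths can have mathematically equal metrics —
  interior paths `(1,0)` and `(0,1)` always do, by symmetry of the branch
  products — and accumulation order can leave them a few ulps apart. Both
  decoding routes therefore treat log-metrics within `1e-9` as tied and
  return the lexicographically smallest path (0 before 1, read from the
  left). At the parameter values used anywhere in the package,
  mathematically distinct metrics differ by far more than the tolerance.
* **Boundary zero-runs.** Leading/trailing zero-runs have no flanking 1 on
  one side; decoding them would need the unconditioned initial law and is
  not part of the model. They are left as zeros by `smap_decode()`,
  `threshold_fill()` and `antagonistic_fill()` alike, and the enumeration
  oracle constrains itself to the same convention by default (its
  unconstrained mode, which applies the stationary prior to $m_1$, agrees
  with the trellis wherever the daughter starts and ends in a 1).
* **Memoization.** The decoded interior for a flanked run depends only on
  `(alpha, beta, retention, k)`, so `decode_segment()` caches it; decoding
  an ensemble of daughters costs one Viterbi pass per distinct gap length.
* **Seeds.** Every stochastic entry point takes one seed; ensembles derive
  a deterministic child seed per element, so element `i` of a simulation
  is reproducible regardless of how many elements are requested, and
  seeded calls never disturb the caller's RNG stream.
* **Degenerate inputs.** `alpha` or `beta` of exactly 0 or 1 are legal for
  simulation (absorbing/alternating chains, with classed conditions where
  a quantity such as a mean run length or the stationary law stops being
  defined); `k_star()` and `classify_region()` require interior
  parameters.

## Two antagonistic marks

For a pair of mutually exclusive marks (say H3K27me3 and H3K36me) the
mother is a ternary sequence over $\{0, 1, 2\}$. Replication erases either
mark with the same coin; correction applies the threshold rule once per
mark, each enzyme seeing the other mark's nucleosomes as unmodified.
`antagonistic_fill()` reads the flanks from the *original* daughter for
both marks, which makes the two enzymes' actions commute and makes
conflicting fills impossible (a zero-run cannot be concordantly flanked by
1s and by 2s at once). `make_ternary_mother()` builds fully covered
mothers by relabelling a binary chain's 1-runs and 0-runs as marks 1
and 2; full coverage is what makes the uncorrected daughter error
concentrate at $1 - r \approx 0.5$. A variant with genuine unmarked
stretches is available via `gap_params` but is not the default, since the
headline uncorrected-error level requires near-complete coverage.

## Fidelity metrics

`ber()` is the mismatch fraction $\Delta(M, \hat M) = \frac1N \sum_i
(m_i - \hat m_i)^2$ (for ternary sequences any symbol mismatch counts 1;
no weighted variant is defined because none is needed by the analyses).
`block_error()` averages $|$block density difference$|$ over consecutive
blocks, reducing exactly to `ber()` at block size 1 and never exceeding
it; the trailing short block is averaged with its true length. The exact
block-error formula is our reading of "error averaged over blocks of
neighbouring nucleosomes", pinned down by the required block-1 identity.
`occupancy_profile()` gives the population-averaged per-position mean.

## The data arm and what the synthetic generators do (and do not) emulate

Experimental occupancy is population-averaged. `normalize_track()` maps a
non-negative signal to $[0, 1]$ by its maximum (or a user saturation
constant — the minimal choice consistent with a randomized, single-cell-
like binarization; a quantile rescaling would also be defensible and is
deliberately left to the user via `saturation`). `discretize_track()`
draws each position independently as Bernoulli(track value). Two caveats
are intentional and tested rather than hidden:

* Realizations carry **no positional correlation beyond the track's own
  island structure**: a flat track at 0.5 yields IID coin flips and
  estimates $\hat\alpha \approx \hat\beta \approx 0.5$ no matter what
  chain produced the population average. Parameter recovery through
  `estimate_from_track()` is meaningful only for island-structured
  tracks.
* The synthetic generators (`make_two_level_track()`,
  `make_bistable_ensemble()`, `make_ternary_mother()`) emulate island
  geometry, bistable ensembles and alternating-domain mothers, not
  read-level ChIP noise, replicate variability or nucleosome-positioning
  uncertainty. Tests passing on them show the decoding theory and its
  implementation are correct, not that any particular genomic locus obeys
  a first-order chain.

## Problem sizes and reproducibility of the shipped analyses

The experiment drivers default to desk-scale ensembles chosen so a full
run of every analysis finishes in minutes on one core: heatmaps at 30
mothers × 20 daughters × length 1000 (a `full = TRUE` flag restores the
publication-scale 300 × 200), threshold sweeps over $k_t = 0..12$, the
track pipeline at 100 × 100, the antagonistic run at 200 daughters of
length 500, and multi-generation runs over 5 generations with block sizes
1/5/10/25. These sizes are stated here as the package's defaults; all of
them are arguments.

## Known limitations

* Multi-generation fidelity is limited by **island-end erosion**: filling
  restores zeros only *between* surviving marks, so a modified island
  loses on average one nucleosome per end per generation (the expected
  geometric overhang at $r = 1/2$) and no decoder consistent with the
  boundary convention can recover it. At $\alpha = \beta = 0.9$,
  $k_t = 6$, the mean bit error against the original mother grows from
  about 0.11 after one generation to about 0.30 after five, even though
  the block error at coarse scales stays visibly lower — the spatial
  pattern degrades more slowly than the bitwise one. Long-horizon
  inheritance in this framework needs secondary mechanisms (boundary
  elements, nucleation sites) outside the model's scope.
* Decoding is sequence-MAP only; per-site posterior-marginal (BCJR-style)
  decoding would minimize BER directly and is a possible extension, not
  implemented.
* Sequences are binary/ternary per mark; higher-order or nonhomogeneous
  chains, enzyme kinetics and polymer/phase-separation effects are out of
  scope.

## A worked session

```{r example, eval = FALSE}
m <- epimarkov(0.9, 0.9)
summary(m)

mom <- simulate(m, nsim = 1, n = 1000, seed = 1)[[1]]
d <- replicate_chromatin(mom, seed = 2)
ber(mom, d)                                    # ~0.25 uncorrected
ber(mom, predict(m, d, method = "smap"))       # ~0.1 decoded

sweep <- run_threshold_sweep(0.9, 0.9, seed = 3)
attr(sweep, "argmin")                          # 6 = floor(k*)
```
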