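test_that("branch metrics multiply transition and channel probabilities", {
  m <- epimarkov(0.9, 0.9)
  expect_equal(branch_metric(m, 1, 1, 0), 0.45)
  expect_equal(branch_metric(m, 1, 0, 0), 0.1)
  expect_equal(branch_metric(m, 0, 0, 0), 0.9)
  expect_equal(branch_metric(m, 0, 1, 1), 0.05)
  # the channel cannot create marks
  expect_equal(branch_metric(m, 0, 0, 1), 0)
  expect_equal(branch_metric(m, 1, 0, 1), 0)
  # cross-check against the first-principles oracle on a parameter sweep
  for (a in c(0.2, 0.7)) for (b in c(0.3, 0.9)) for (r in c(0.3, 0.5))
    for (mp in 0:1) for (mm in 0:1) for (d in 0:1)
      expect_equal(branch_metric(epimarkov(a, b), mp, mm, d, retention = r),
                   oracle_trans(a, b, mp, mm) * oracle_chan(r, mm, d))
})

test_that("daughters decompose into flanked zero-runs only", {
  s <- segment_decompose(c(1, 0, 0, 1, 0, 1))
  expect_equal(s$k, c(2L, 1L))
  expect_equal(s$start, c(1L, 4L))
  expect_equal(s$end, c(4L, 6L))
  expect_equal(nrow(segment_decompose(c(0, 0, 1, 1, 0, 0))), 0L)
  expect_equal(nrow(segment_decompose(c(1, 1, 1))), 0L)
  expect_equal(nrow(segment_decompose(rep(0L, 5))), 0L)
  # segments are disjoint and ordered
  d <- c(0, 1, 0, 0, 0, 1, 1, 0, 1, 0, 0)
  s <- segment_decompose(d)
  expect_equal(s$k, c(3L, 1L))
  expect_true(all(diff(as.vector(rbind(s$start, s$end))) >= 0))
})

test_that("segment decoding equals exhaustive enumeration over 2^k paths", {
  m <- epimarkov(0.9, 0.9)
  expect_equal(decode_segment(m, 3), rep(1L, 3))
  expect_equal(decode_segment(m, 10), rep(0L, 10))
  # with a perfect channel an observed 0 is a true 0
  expect_equal(decode_segment(epimarkov(0.7, 0.6), 4, retention = 1),
               rep(0L, 4))
  # oracle sweep, including region-d parameters where intermediate paths tie
  set.seed(101)
  for (i in 1:60) {
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
    k <- sample(1:8, 1)
    expect_equal(decode_segment(epimarkov(a, b), k), oracle_segment(a, b, 0.5, k),
                 info = sprintf("a=%.3f b=%.3f k=%d", a, b, k))
  }
})

test_that("whole-sequence decoding preserves ones and fills only flanked runs", {
  m <- epimarkov(0.9, 0.9)
  expect_equal(smap_decode(m, rep(1L, 6)), rep(1L, 6))
  expect_equal(smap_decode(m, c(1, 0, 0, 0, 1)), rep(1L, 5))
  expect_equal(smap_decode(m, rep(0L, 6)), rep(0L, 6))
  # monotone trust: observed ones never flip, boundary zero-runs never fill
  set.seed(202)
  for (i in 1:50) {
    mm <- epimarkov(runif(1, 0.1, 0.95), runif(1, 0.1, 0.95))
    d <- sample(0:1, 30, replace = TRUE)
    out <- smap_decode(mm, d)
    expect_true(all(out >= d))
    first1 <- match(1L, d); last1 <- length(d) + 1L - match(1L, rev(d))
    if (!is.na(first1)) {
      if (first1 > 1) expect_equal(out[1:(first1 - 1)], d[1:(first1 - 1)])
      if (last1 < length(d))
        expect_equal(out[(last1 + 1):length(d)], d[(last1 + 1):length(d)])
    }
  }
})

test_that("trellis decoding equals the exhaustive MAP oracle", {
  # random instances with flanking ones (free and convention modes agree)
  set.seed(303)
  for (i in 1:200) {
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
    n <- sample(3:14, 1)
    d <- c(1L, sample(0:1, n - 2, replace = TRUE), 1L)
    mm <- epimarkov(a, b)
    got <- smap_decode(mm, d)
    expect_equal(got, brute_force_map(mm, d), info = paste(d, collapse = ""))
    expect_equal(got, brute_force_map(mm, d, boundary = "free"),
                 info = paste(d, collapse = ""))
  }
  # arbitrary daughters (boundary zero-runs present) against the
  # convention-constrained oracle
  set.seed(304)
  for (i in 1:200) {
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
    n <- sample(2:14, 1)
    d <- sample(0:1, n, replace = TRUE)
    mm <- epimarkov(a, b)
    expect_equal(smap_decode(mm, d), brute_force_map(mm, d),
                 info = paste(d, collapse = ""))
  }
  expect_error(brute_force_map(epimarkov(0.5, 0.5), rep(1L, 21)), "N > 20")
})

test_that("per-segment decoding is sound against joint enumeration", {
  # crafted multi-segment daughters: joint exhaustive MAP must equal the
  # concatenation of independent segment decodes
  m <- epimarkov(0.85, 0.9)
  for (d in list(c(1, 0, 1, 0, 0, 1), c(1, 0, 0, 1, 1, 0, 0, 0, 1),
                 c(1, 0, 1, 0, 1, 0, 1))) {
    d <- as.integer(d)
    expect_equal(smap_decode(m, d), brute_force_map(m, d, boundary = "free"))
  }
  # smallest interesting case: (1,0,1) -> (1,1,1) whenever g_1 > 0
  for (ab in list(c(0.9, 0.9), c(0.8, 0.6), c(0.95, 0.4))) {
    mm <- epimarkov(ab[1], ab[2])
    expect_gt(g_k(mm, 1), 0)
    expect_equal(brute_force_map(mm, c(1L, 0L, 1L)), c(1L, 1L, 1L))
  }
})
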