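test_that("g_k matches the printed closed form and its sign structure", {
  m <- epimarkov(0.9, 0.9)
  expect_equal(g_k(m, 1), 0.1975)
  # general k form agrees with the retention-1/2 expression
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0.05, 0.99); b <- runif(1, 0.05, 0.99); k <- sample(1:10, 1)
    expect_equal(g_k(epimarkov(a, b), k),
                 (a / 2)^(k + 1) - 0.5 * (1 - a) * b^(k - 1) * (1 - b))
    # g_1 reduces to alpha^2/4 - (1-alpha)(1-beta)/2
    expect_equal(g_k(epimarkov(a, b), 1), a^2 / 4 - (1 - a) * (1 - b) / 2)
  }
  # alpha = 0: filling is never preferred
  expect_true(all(vapply(1:10, function(k) g_k(epimarkov(0, 0.5), k),
                         numeric(1)) < 0))
  # bracketing of the root at alpha = beta = 0.9
  expect_gt(g_k(m, 6), 0)
  expect_lt(g_k(m, 7), 0)
})

test_that("k_star is the root of g_k and brackets correctly", {
  m <- epimarkov(0.9, 0.9)
  expect_equal(k_star(m), 6.34, tolerance = 1e-3)
  # independent bisection on g_k treating k as real
  root <- uniroot(function(k) g_k(m, k), c(1, 50), tol = 1e-12)$root
  expect_equal(k_star(m), root, tolerance = 1e-9)
  # random region-b parameters: closed form vs numeric root, and the
  # integer bracketing g(floor) > 0 >= g(floor + 1)
  set.seed(21)
  for (i in 1:50) {
    mm <- random_region_b()
    ks <- k_star(mm)
    up <- 2
    while (g_k(mm, up) > 0) up <- up * 2
    root <- uniroot(function(k) g_k(mm, k), c(1, up), tol = 1e-12)$root
    expect_equal(ks, root, tolerance = 1e-9)
    if (ks >= 1) {
      expect_gt(g_k(mm, max(floor(ks), 1)), 0)
      expect_lt(g_k(mm, floor(ks) + 1), 0)
    }
  }
  expect_error(k_star(epimarkov(0.9, 0.45)), class = "epifill_no_finite_root")
  expect_error(k_star(epimarkov(0.1, 0.9)), class = "epifill_not_fillable")
})

test_that("the parameter square is partitioned into regions a-d", {
  expect_equal(classify_region(epimarkov(0.9, 0.1)), "a")
  expect_equal(classify_region(epimarkov(0.9, 0.9)), "b")
  expect_equal(classify_region(epimarkov(0.1, 0.9)), "c")
  expect_equal(classify_region(epimarkov(0.5, 0.05)), "d")
  # sign checks defining those examples
  expect_gt(g_k(epimarkov(0.9, 0.1), 1), 0)
  expect_lt(g_k(epimarkov(0.5, 0.05), 1), 0)
  # every interior point gets exactly one label
  set.seed(31)
  for (i in 1:100) {
    lab <- classify_region(epimarkov(runif(1, 0.01, 0.99),
                                     runif(1, 0.01, 0.99)))
    expect_true(lab %in% c("a", "b", "c", "d"))
  }
})

test_that("threshold filling fills flanked runs up to k_t and is idempotent", {
  expect_equal(threshold_fill(c(1, 0, 0, 1, 0, 0, 0, 1), 2),
               c(1, 1, 1, 1, 0, 0, 0, 1))
  expect_equal(threshold_fill(c(0, 1, 0, 1, 0), 5), c(0, 1, 1, 1, 0))
  d <- c(1, 0, 1, 1, 0, 0, 1, 0, 0, 0, 0, 1)
  expect_identical(threshold_fill(d, 0), as.integer(d))
  for (kt in 0:5) {
    once <- threshold_fill(d, kt)
    expect_identical(threshold_fill(once, kt), once)
  }
  expect_equal(fill_all(c(1, 0, 0, 0, 0, 0, 0, 1)), rep(1L, 8))
  expect_equal(fill_all(rep(0L, 4)), rep(0L, 4))
  expect_equal(fill_all(c(0, 0, 1, 0, 1, 0, 0)), c(0, 0, 1, 1, 1, 0, 0))
  expect_identical(fill_all(d), threshold_fill(d, Inf))
})

test_that("in region b the threshold rule reproduces SMAP segment-by-segment", {
  for (ab in list(c(0.8, 0.9), c(0.9, 0.9), c(0.85, 0.95))) {
    m <- epimarkov(ab[1], ab[2])
    expect_equal(classify_region(m), "b")
    kt <- floor(k_star(m))
    for (k in 1:30) {
      expected <- if (k <= kt) rep(1L, k) else rep(0L, k)
      expect_equal(decode_segment(m, k), expected,
                   info = sprintf("alpha=%.2f beta=%.2f k=%d", ab[1], ab[2], k))
    }
  }
})

test_that("in region a SMAP fills every flanked run", {
  for (ab in list(c(0.9, 0.1), c(0.8, 0.3))) {
    m <- epimarkov(ab[1], ab[2])
    expect_equal(classify_region(m), "a")
    for (k in c(1:12, 30))
      expect_equal(decode_segment(m, k), rep(1L, k))
    # on whole daughters: fill_all == smap_decode
    for (i in 1:30) {
      mom <- generate_mother(m, 200, seed = i)
      d <- replicate_chromatin(mom, seed = 100 + i)
      expect_identical(smap_decode(m, d), fill_all(d))
    }
  }
})

test_that("antagonistic filling acts per modification on the original daughter", {
  expect_equal(antagonistic_fill(c(1, 0, 0, 1, 2, 0, 2), 2),
               c(1, 1, 1, 1, 2, 2, 2))
  expect_equal(antagonistic_fill(c(1, 0, 2), 10), c(1, 0, 2))
  expect_equal(antagonistic_fill(c(1, 0, 0, 0, 1), 2), c(1, 0, 0, 0, 1))
  expect_equal(antagonistic_fill(c(1, 0, 0, 0, 1), 3), rep(1L, 5))
  # boundary runs untouched; zeros beyond threshold untouched
  expect_equal(antagonistic_fill(c(0, 2, 0, 2, 0), 1), c(0, 2, 2, 2, 0))
  # idempotent, and the binary special case agrees with threshold_fill
  set.seed(41)
  for (i in 1:30) {
    d <- sample(0:2, 40, replace = TRUE)
    once <- antagonistic_fill(d, 3)
    expect_identical(antagonistic_fill(once, 3), once)
    b <- sample(0:1, 40, replace = TRUE)
    expect_identical(antagonistic_fill(b, 4), threshold_fill(b, 4))
  }
})
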