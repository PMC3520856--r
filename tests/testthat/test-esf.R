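# elementary symmetric functions: oracle equivalence, stability,
# and the Newton's-identity cancellation demonstration

test_that("small closed-form ESF values are reproduced by every route", {
  # single leaf
  expect_equal(as.numeric(esf_bruteforce(7)), c(1, 7))
  expect_equal(as.numeric(esf_newton(7)), c(1, 7))
  expect_equal(as.numeric(esf_split_merge(7)), c(1, 7))
  # enumerated 2^3 subsets of {1,2,3}: e = (1, 6, 11, 6)
  for (f in list(esf_bruteforce,
                 function(w) esf_newton(w, "extended"),
                 esf_split_merge)) {
    expect_equal(as.numeric(f(c(1, 2, 3))), c(1, 6, 11, 6))
  }
  # equal weights give binomial coefficients times c^k
  expect_equal(as.numeric(esf_bruteforce(rep(1, 4))), choose(4, 0:4))
  expect_equal(as.numeric(esf_split_merge(rep(2, 6))),
               choose(6, 0:6) * 2^(0:6))
  # a zero weight kills the top coefficient
  e <- as.numeric(esf_split_merge(c(3, 0, 5)))
  expect_identical(e[4], 0)
})

test_that("split-merge matches subset enumeration for random wide-range weights", {
  for (s in 1:40) {
    m <- 3 + (s %% 18)
    w <- random_weights(m, seed = s)
    bf <- as.numeric(esf_bruteforce(w))
    sm <- as.numeric(esf_split_merge(w))
    expect_lt(max(rel_err(sm, bf)), 1e-12)
  }
})

test_that("generating-polynomial identity holds on every ESF route", {
  for (s in 1:10) {
    w <- random_weights(10, seed = 100 + s)
    for (e in list(esf_bruteforce(w), esf_split_merge(w))) {
      expect_equal(sum(as.numeric(e)), prod(1 + w),
                   tolerance = 1e-12)
    }
    expect_equal(as.numeric(esf_split_merge(w))[11], prod(w),
                 tolerance = 1e-12)
    expect_identical(as.numeric(esf_split_merge(w))[1], 1)
    # the Newton recursion cancels terms ~ (max w / geomean w)^k, so its
    # extended mode is held to weight sets its 31-digit headroom covers
    wm <- random_weights(10, seed = 100 + s, orders = 3)
    expect_equal(sum(as.numeric(esf_newton(wm, "extended"))),
                 prod(1 + wm), tolerance = 1e-12)
  }
})

test_that("split-merge is invariant under weight permutation", {
  for (s in 1:10) {
    w <- random_weights(13, seed = 200 + s)
    a <- as.numeric(esf_split_merge(w))
    b <- as.numeric(esf_split_merge(withr::with_seed(s, sample(w))))
    expect_lt(max(rel_err(b, a)), 1e-12)
  }
})

test_that("merge convolves subsystem ESFs and multiplies their totals", {
  expect_equal(as.numeric(esf_merge(esf_empty(), esf_from_weights(4))),
               c(1, 4))
  expect_equal(as.numeric(esf_merge(esf_from_weights(2),
                                    esf_from_weights(3))),
               c(1, 5, 6))
  for (s in 1:8) {
    a <- esf_split_merge(random_weights(5, seed = 300 + s))
    b <- esf_split_merge(random_weights(7, seed = 400 + s))
    m <- esf_merge(a, b)
    expect_length(m, length(a) + length(b) - 1)
    expect_equal(sum(as.numeric(m)),
                 sum(as.numeric(a)) * sum(as.numeric(b)),
                 tolerance = 1e-12)
  }
})

test_that("all routes agree in extended arithmetic for moderate weights", {
  for (s in 1:10) {
    w <- random_weights(8 + s %% 8, seed = 500 + s, orders = 2)
    bf <- as.numeric(esf_bruteforce(w))
    expect_lt(max(rel_err(as.numeric(esf_newton(w, "extended")), bf)), 1e-12)
    expect_lt(max(rel_err(as.numeric(esf_split_merge(w)), bf)), 1e-12)
  }
})

test_that("machine-double Newton cancels catastrophically on the packaged fixture", {
  w <- cancellation_weights()
  path <- system.file("extdata", "cancellation_weights.tsv",
                      package = "diapart")
  shipped <- as.numeric(readLines(path)[-(1:2)])
  expect_equal(shipped, w, tolerance = 1e-15)
  ref <- as.numeric(esf_newton(w, "extended"))     # dd oracle
  bf <- as.numeric(esf_bruteforce(w))              # exact enumeration
  expect_lt(max(rel_err(ref, bf)), 1e-12)          # oracle is trustworthy here
  bad <- as.numeric(esf_newton(w, "double"))
  expect_gt(max(rel_err(bad, ref)), 1e-2)          # the cancellation
  sm <- as.numeric(esf_split_merge(w))
  expect_lt(max(rel_err(sm, ref)), 1e-10)          # split-merge unaffected
})

test_that("log-domain representation survives magnitudes far beyond doubles", {
  lw <- withr::with_seed(9, runif(400, -30, 30) * 40)  # logs to +-1200
  e <- esf_split_merge(log_w = lw)
  expect_true(all(is.finite(log_coeffs(e)[is.finite(log_coeffs(e))])))
  # generating identity in the log domain
  expect_equal(diapart:::logsumexp(log_coeffs(e)),
               sum(log1p(exp(-abs(lw))) + pmax(lw, 0)),
               tolerance = 1e-10)
  expect_error(as.numeric(e), "double range")
})

test_that("misuse guards fire", {
  expect_error(esf_bruteforce(rep(1, 26)), "M <= 25")
  expect_error(esf_bruteforce(c(1, -2)), "finite and >= 0")
  expect_error(esf_split_merge(numeric(0)), "non-empty")
  expect_error(esf_newton(exp(seq(600, 700, length.out = 5))), "overflow")
})
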