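test_that("constant-rate ZMG matches closed forms and special cases", {
  ## frozen values, originally derived by forward Monte-Carlo (see the
  ## MC grid test below for the live simulation cross-check)
  z <- zmg_const(1, 0.1, 1)
  expect_equal(z$a, 0.0618580, tolerance = 1e-6)
  expect_equal(z$b, 0.6185799, tolerance = 1e-6)

  ## dt = 0: point mass at one descendant
  z0 <- zmg_const(2, 0.7, 0)
  expect_identical(c(z0$a, z0$b), c(0, 0))
  expect_equal(zmg_pmf(z0, 0:2), c(0, 1, 0))

  ## critical case
  zc <- zmg_const(1, 1, 1)
  expect_equal(c(zc$a, zc$b), c(0.5, 0.5))

  ## Yule: a = 0, b = 1 - exp(-lambda dt)
  zy <- zmg_const(1, 0, log(2))
  expect_equal(c(zy$a, zy$b), c(0, 0.5))

  expect_error(zmg_const(1, 0.1, -1), "dt")
  expect_error(zmg_const(0, 0.1, 1), "lambda")
})

test_that("ZMG pmf is a proper distribution and continuous at criticality", {
  for (par in list(c(0.7, 0.3, 2), c(1, 1, 1.5), c(2, 0, 0.4))) {
    z <- zmg_const(par[1], par[2], par[3])
    expect_equal(sum(zmg_pmf(z, 0:2000)), 1, tolerance = 1e-10)
  }
  for (t in c(0.5, 1, 3)) {
    up <- zmg_const(1, 1 + 1e-9, t)
    dn <- zmg_const(1, 1 - 1e-9, t)
    at <- zmg_const(1, 1, t)
    expect_lt(max(abs(zmg_pmf(up, 0:10) - zmg_pmf(at, 0:10))), 1e-6)
    expect_lt(max(abs(zmg_pmf(dn, 0:10) - zmg_pmf(at, 0:10))), 1e-6)
  }
})

test_that("composition: identities, absorption, semigroup property", {
  x <- zmg_const(0.8, 0.3, 1.2)
  id <- zmg_const(1, 0, 0) # a = 0, b = 0
  expect_equal(zmg_compose(x, id)$a, x$a, tolerance = 1e-14)
  expect_equal(zmg_compose(x, id)$b, x$b, tolerance = 1e-14)

  dead <- structure(list(a = 1, b = 0), class = "zmg")
  comp <- zmg_compose(x, dead)
  expect_identical(c(comp$a, comp$b), c(1, 0))

  ## semigroup: splitting a homogeneous interval changes nothing
  direct <- zmg_const(1, 0.1, 1.0)
  split <- zmg_compose(zmg_const(1, 0.1, 0.7), zmg_const(1, 0.1, 0.3))
  expect_equal(split$a, direct$a, tolerance = 1e-10)
  expect_equal(split$b, direct$b, tolerance = 1e-10)
  set.seed(42)
  for (i in 1:20) {
    lam <- runif(1, 0.2, 2); mu <- runif(1, 0, 1.5)
    d1 <- runif(1, 0, 2); d2 <- runif(1, 0, 2)
    direct <- zmg_const(lam, mu, d1 + d2)
    split <- zmg_compose(zmg_const(lam, mu, d1), zmg_const(lam, mu, d2))
    expect_equal(split$a, direct$a, tolerance = 1e-10)
    expect_equal(split$b, direct$b, tolerance = 1e-10)
  }
})

test_that("closed-form composition equals numeric convolution", {
  cases <- list(list(c(0.8, 0.3, 0.9), c(1.2, 0.5, 0.6)),
                list(c(1.0, 0.0, 0.5), c(0.5, 0.4, 1.0)),
                list(c(1.0, 1.0, 0.8), c(1.0, 1.0, 0.8)))
  for (cs in cases) {
    zo <- do.call(zmg_const, as.list(cs[[1]]))
    zy <- do.call(zmg_const, as.list(cs[[2]]))
    zc <- zmg_compose(zo, zy)
    num <- oracle_compose_pmf(zo, zy, kmax = 50)
    expect_lt(max(abs(num - zmg_pmf(zc, 0:50))), 1e-12)
  }
})

test_that("pk_skyline reduces, normalizes, and ignores spurious shifts", {
  m1 <- skyline_model(1, 0.1)
  expect_equal(pk_skyline(m1, 1, 0), zmg_const(1, 0.1, 1)$a,
               tolerance = 1e-14)

  ## two intervals with identical rates = one interval, many (t, k)
  m2 <- skyline_model(c(1, 1), c(0.1, 0.1), 0.6)
  for (t in c(0.2, 0.6, 1, 4))
    expect_equal(pk_skyline(m2, t, 0:8), pk_skyline(m1, t, 0:8),
                 tolerance = 1e-12)

  ## property: inserting a spurious shift into random skyline models
  set.seed(7)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    ts <- sort(runif(k, 0.2, 4))
    lam <- runif(k + 1, 0.2, 2); mu <- runif(k + 1, 0, 1.5)
    m <- skyline_model(lam, mu, ts)
    ins <- sample(k + 1, 1) # duplicate rates around a new boundary
    tnew <- runif(1, c(0, ts)[ins], c(ts, 5)[ins])
    if (any(abs(tnew - ts) < 1e-9)) next
    ts2 <- sort(c(ts, tnew))
    pos <- which(ts2 == tnew)
    m2 <- skyline_model(append(lam, lam[pos], after = pos - 1),
                        append(mu, mu[pos], after = pos - 1), ts2)
    t <- runif(1, 0, 6)
    expect_equal(pk_skyline(m2, t, 0:6), pk_skyline(m, t, 0:6),
                 tolerance = 1e-11)
  }

  ## normalization across random models
  set.seed(8)
  for (i in 1:10) {
    m <- skyline_model(runif(2, 0.3, 1.5), runif(2, 0, 1), runif(1, 0.5, 2))
    z <- skyline_zmg(m, runif(1, 0.1, 5))
    expect_equal(z$a + (1 - z$a), 1)
    expect_equal(sum(zmg_pmf(z, 0:5000)), 1, tolerance = 1e-9)
  }
})

test_that("p_survival behaves at the boundaries", {
  m <- skyline_model(1, 0.1)
  expect_equal(p_survival(m, 0), 1)
  expect_equal(p_survival(m, 1), 1 - 0.0618580, tolerance = 1e-5)
  myule <- skyline_model(c(0.7, 1.2), c(0, 0), 1)
  expect_equal(p_survival(myule, c(0.5, 2, 10)), rep(1, 3))
})

test_that("closed-form p_k matches forward Monte-Carlo on a rate grid", {
  ## scaled down from a full factorial sweep to keep runtime sane: 3x3x3
  ## grid with lambda * t <= 2.4, 2e4 replicates, binomial 4-sigma bands
  set.seed(123)
  reps <- 2e4
  for (lam in c(0.3, 1, 2)) for (mu in c(0, 0.5, 1.5)) {
    for (t in c(0.1, 0.5, 1.2)) {
      if (lam * t > 2.4) next
      m <- skyline_model(lam, mu)
      cnt <- rbd_count(m, t, reps)
      for (k in c(0, 1, 2, 5)) {
        p <- pk_skyline(m, t, k)
        se <- sqrt(max(p * (1 - p), 1e-12) / reps)
        expect_lt(abs(mean(cnt == k) - p), 4 * se + 1e-9)
      }
    }
  }
})

test_that("skyline p_k with a genuine shift matches Monte-Carlo", {
  set.seed(321)
  m <- skyline_model(c(0.5, 1), c(0.1, 0.4), 2)
  reps <- 1e5
  cnt <- rbd_count(m, 3, reps)
  for (k in 0:5) {
    p <- pk_skyline(m, 3, k)
    se <- sqrt(p * (1 - p) / reps)
    expect_lt(abs(mean(cnt == k) - p), 4 * se)
  }
})
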