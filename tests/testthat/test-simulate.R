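test_that("sim_free degenerate and bookkeeping cases", {
  mod <- skyline_model(1, 0.5)
  tr <- sim_free(mod, 0, seed = 1)
  expect_equal(sum(tr$extant), 1)
  expect_false(attr(tr, "all_extinct"))
  expect_equal(attr(tr, "stem_age"), 0)

  set.seed(2)
  trs <- replicate(50, sim_free(skyline_model(0.5, 1.5), 2), simplify = FALSE)
  flags <- vapply(trs, function(t) attr(t, "all_extinct"), TRUE)
  expect_true(any(flags)) # high extinction: most runs die out
  ## extinct tips carry positive age, extant tips age ~ 0
  ok <- vapply(trs, function(t) {
    if (is.null(t$phy)) return(TRUE)
    all(abs(t$age[seq_along(t$extant)][t$extant]) < 1e-9)
  }, TRUE)
  expect_true(all(ok))
})

test_that("sim_free mean extant count matches the Yule expectation", {
  ## E[N] = exp(lambda t) under pure birth; 2000 reps, 4-sigma band
  set.seed(3)
  lam <- 1; t <- 1.2
  n <- replicate(2000, sum(sim_free(skyline_model(lam, 0), t)$extant))
  expect_lt(abs(mean(n) - exp(lam * t)), 4 * sd(n) / sqrt(2000))
})

test_that("sim_free extinction fraction matches p_0", {
  set.seed(4)
  mod <- skyline_model(1, 0.1)
  ext <- replicate(3000, attr(sim_free(mod, 1), "all_extinct"))
  p0 <- pk_skyline(mod, 1, 0)
  expect_lt(abs(mean(ext) - p0), 3 * sqrt(p0 * (1 - p0) / 3000))
})

test_that("sim_free extant-count pmf matches pk_skyline under a shift", {
  ## the central cross-module oracle: forward simulation vs closed form,
  ## chi-squared goodness of fit on counts {0, 1, 2, 3, 4+}
  set.seed(5)
  mod <- skyline_model(c(0.9, 0.4), c(0.2, 0.1), 0.8)
  t0 <- 2
  reps <- 3000
  n <- replicate(reps, sum(sim_free(mod, t0)$extant))
  obs <- c(sum(n == 0), sum(n == 1), sum(n == 2), sum(n == 3), sum(n >= 4))
  p <- pk_skyline(mod, t0, 0:3)
  expected <- reps * c(p, 1 - sum(p))
  chi <- sum((obs - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 4, lower.tail = FALSE), 0.001)
})

test_that("conditioned simulation: exact n, ultrametric, deterministic", {
  mod <- skyline_model(c(0.5, 1), c(0.1, 0.1), 2)
  tr <- sim_conditioned(mod, 200, seed = 6)
  expect_equal(sum(tr$extant), 200)
  expect_length(tr$phy$tip.label, 200)
  tip_ages <- tr$age[seq_len(200)]
  expect_lt(max(abs(tip_ages)), 1e-6 * tr$root_age)

  expect_identical(write_newick(sim_conditioned(mod, 50, seed = 9)),
                   write_newick(sim_conditioned(mod, 50, seed = 9)))
  expect_error(sim_conditioned(mod, 1), "n >= 2")
})

test_that("conditioned Yule crown age matches the harmonic expectation", {
  ## E[age] = sum_{k=2}^{n} 1/(k lambda) under the uniform age prior
  set.seed(7)
  n <- 100; lam <- 1
  ages <- replicate(400, sim_conditioned(skyline_model(lam, 0), n)$root_age)
  expect_lt(abs(mean(ages) - sum(1 / (2:n * lam))),
            4 * sd(ages) / sqrt(400))
})

test_that("conditioned trees match forward simulation (rejection oracle)", {
  ## constant rates, stem age fixed: among forward runs with exactly 2
  ## extant species, the reconstructed branching time has CDF b(x)/b(x0);
  ## this exercises likelihood, sampler maths and simulator together
  set.seed(8)
  mod <- skyline_model(1, 0.3)
  x0 <- 1.5
  acc <- numeric(0)
  for (i in 1:8000) {
    tr <- sim_free(mod, x0)
    if (!is.null(tr$phy) && sum(tr$extant) == 2)
      acc <- c(acc, branching_times(reconstructed(tr))[1])
  }
  expect_gt(length(acc), 500)
  bfun <- function(x) vapply(x, function(t) skyline_zmg(mod, t)$b, 0)
  u <- bfun(acc) / bfun(x0) # should be uniform on (0, 1)
  obs <- tabulate(cut(u, seq(0, 1, 0.2)), 5)
  chi <- sum((obs - length(u) / 5)^2 / (length(u) / 5))
  expect_gt(pchisq(chi, df = 4, lower.tail = FALSE), 0.001)
})

test_that("collapse on the toy tree (hand-computed)", {
  tr <- toy_tree() # branchings at 4, 3, 2
  ## x_cut = 2.5: lineages crossing are A, B (split at 3 is older) and
  ## the (C,D) clade -> 3 tips
  res <- collapse_tree(tr, 2.5)
  expect_equal(unname(res$sizes[sort(names(res$sizes))]), c(1L, 1L, 2L))
  expect_named(res$sizes[sort(names(res$sizes))], c("A", "B", "C"))
  expect_equal(res$hlt$branching_times, c(4, 3))
  expect_equal(res$hlt$m, 4L)

  ## x_cut = 3.5: only the root is older -> 2 clades of 2
  res2 <- collapse_tree(tr, 3.5)
  expect_equal(sort(unname(res2$sizes)), c(2L, 2L))
  expect_equal(res2$hlt$branching_times, 4)

  ## below all branchings: unchanged, unit sizes
  res3 <- collapse_tree(tr, 1.0)
  expect_equal(unname(res3$sizes), rep(1L, 4))
  expect_equal(res3$hlt$branching_times, c(4, 3, 2))
  res0 <- collapse_tree(tr, 0)
  expect_equal(res0$hlt$m, 4L)

  expect_error(collapse_tree(tr, 2.0), "collides")
})

test_that("collapse conserves species and round-trips through files", {
  mod <- skyline_model(c(0.5, 1), c(0.1, 0.1), 2)
  tr <- sim_conditioned(mod, 150, seed = 10)
  xc <- quartile_xcut(tr, 0.5)
  res <- collapse_tree(tr, xc)
  expect_equal(res$hlt$m, 150L)
  expect_equal(sum(res$sizes), 150L)
  expect_equal(res$hlt$branching_times,
               branching_times(tr)[branching_times(tr) > xc])

  ## file round trip is bit-identical
  nwk <- withr::local_tempfile(fileext = ".nwk")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_newick(res$tree, nwk)
  write_clade_sizes(res$sizes, tsv)
  tr2 <- read_newick(file = nwk)
  hlt2 <- build_higher_level(tr2, read_clade_sizes(tsv), xc)
  expect_identical(write_newick(tr2), write_newick(res$tree))
  expect_equal(hlt2$branching_times, res$hlt$branching_times,
               tolerance = 1e-9)
  expect_identical(hlt2$m, res$hlt$m)
})

test_that("quartile_xcut nudges off branching-time collisions", {
  tr <- toy_tree() # root age 4, branchings 4, 3, 2
  expect_equal(quartile_xcut(tr, 0.25), 1.0)
  ## 0.5 * 4 = 2 collides -> midpoint of the younger gap (0, 2)
  expect_equal(quartile_xcut(tr, 0.5), 1.0)
  ## 0.75 * 4 = 3 collides -> midpoint of (2, 3)
  expect_equal(quartile_xcut(tr, 0.75), 2.5)
  expect_error(quartile_xcut(tr, 1.2))
})
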