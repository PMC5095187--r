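## Independent oracles used across the test suite. These deliberately do
## NOT share code with the package: constant-rate probabilities are coded
## from the classical closed forms, distribution composition is done by
## numeric convolution, and tree simulation cross-checks use the separate
## Gillespie simulator.

## classical constant-rate descendant probabilities (direct formulas)
oracle_p0 <- function(lambda, mu, t) {
  if (mu == 0) return(rep(0, length(t)))
  r <- lambda - mu
  if (abs(r) < 1e-12) return(lambda * t / (1 + lambda * t))
  E <- exp(-r * t)
  mu * (1 - E) / (lambda - mu * E)
}

oracle_p1 <- function(lambda, mu, t) {
  r <- lambda - mu
  if (abs(r) < 1e-12) return(1 / (1 + lambda * t)^2)
  E <- exp(-r * t)
  r^2 * E / (lambda - mu * E)^2
}

## classical reconstructed-tree log-density under constant rates, crown
## form, coded independently of the ZMG machinery
oracle_const_crown_loglik <- function(x, lambda, mu,
                                      conditioned = TRUE) {
  x <- sort(x, decreasing = TRUE)
  ll <- 2 * log(oracle_p1(lambda, mu, x[1]))
  if (length(x) > 1)
    ll <- ll + sum(log(lambda) + log(oracle_p1(lambda, mu, x[-1])))
  if (conditioned) ll <- ll - 2 * log(1 - oracle_p0(lambda, mu, x[1]))
  ll
}

## numeric composition of two ZMG pmfs by explicit convolution over the
## interface count (truncated; tail mass negligible for the cases used)
oracle_compose_pmf <- function(older, younger, kmax = 50, jmax = 400) {
  po <- zmg_pmf(older, 0:jmax)
  py <- zmg_pmf(younger, 0:kmax)
  out <- numeric(kmax + 1)
  out[1] <- po[1]
  acc <- c(1, rep(0, kmax)) # pmf of sum of j copies of younger, j = 0
  for (j in 1:jmax) {
    acc <- convolve(acc, rev(py), type = "open")[1:(kmax + 1)]
    out <- out + po[j + 1] * acc
    if (po[j + 1] < 1e-16 && j > 5) break
  }
  out
}

## 4-tip toy tree from the I/O examples: branchings at ages 4, 3, 2
toy_newick <- "((A:3,B:3):1,(C:2,D:2):2);"
toy_tree <- function() read_newick(toy_newick)

## complete-tree higher-level wrapper
complete_hlt <- function(tree) {
  labs <- tree$phy$tip.label
  build_higher_level(tree, setNames(rep(1L, length(labs)), labs), 0)
}
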