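## Zero-modified-geometric (ZMG) descendant-count distributions.
##
## For a linear birth-death process the number of extant descendants of a
## single lineage alive at age t is zero-modified geometric:
##   P(0) = a,  P(k) = (1 - a)(1 - b) b^(k-1)  for k >= 1.
## The family is closed under composition across adjacent time intervals
## (the probability generating function is a fractional-linear map, and the
## composition of two such maps is again fractional-linear), which is what
## makes piecewise-constant rates tractable.

## Vectorised internal kernels work on plain (a, b) vectors; the exported
## API wraps them in a tiny "zmg" S3 class.

## a, b for a constant-rate interval of duration dt.
## Stable forms: for r = lambda - mu > 0 use exp(-r dt) (never overflows);
## for r < 0 use exp(r dt); |r| dt < 1e-8 switches to the critical-case
## closed form a = b = lambda dt / (1 + lambda dt) to avoid cancellation.
zmg_const_ab <- function(lambda, mu, dt) {
  n <- max(length(lambda), length(mu), length(dt))
  lambda <- rep_len(lambda, n); mu <- rep_len(mu, n); dt <- rep_len(dt, n)
  r <- lambda - mu
  a <- b <- numeric(n)
  crit <- abs(r * dt) < 1e-8
  if (any(crit)) {
    x <- lambda[crit] * dt[crit]
    ## mu dt in the numerator of `a` keeps the Yule case (mu = 0) exact;
    ## at lambda == mu both reduce to lambda dt / (1 + lambda dt)
    a[crit] <- mu[crit] * dt[crit] / (1 + x)
    b[crit] <- x / (1 + x)
  }
  pos <- !crit & r > 0
  if (any(pos)) {
    em <- exp(-r[pos] * dt[pos])
    den <- lambda[pos] - mu[pos] * em
    a[pos] <- mu[pos] * (1 - em) / den
    b[pos] <- lambda[pos] * (1 - em) / den
  }
  neg <- !crit & r < 0
  if (any(neg)) {
    ep <- exp(r[neg] * dt[neg])
    den <- lambda[neg] * ep - mu[neg]
    a[neg] <- mu[neg] * (ep - 1) / den
    b[neg] <- lambda[neg] * (ep - 1) / den
  }
  list(a = pmin(a, 1), b = pmin(pmax(b, 0), 1 - 1e-16))
}

## Composition of adjacent intervals: `older` spans the more ancient one.
## Each lineage alive at the interface independently produces descendants
## per `younger`. In PGF terms F = F_older o F_younger; the closed form
## uses F(0) and the mean F'(1) = (1-a)/(1-b) to recover (a', b').
zmg_compose_ab <- function(older, younger) {
  ao <- older$a; bo <- older$b; ai <- younger$a; bi <- younger$b
  a2 <- ao + (1 - ao) * (1 - bo) * ai / (1 - bo * ai)
  mean2 <- (1 - ao) / (1 - bo) * (1 - ai) / (1 - bi)
  b2 <- 1 - (1 - a2) / mean2
  dead <- a2 >= 1
  a2[dead] <- 1
  b2[dead] <- 0
  list(a = a2, b = pmin(pmax(b2, 0), 1 - 1e-16))
}

new_zmg <- function(a, b) {
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "zmg")
}

#' Zero-modified-geometric descendant-count distribution
#'
#' `zmg_const()` gives the distribution of the number of extant descendants
#' of one lineage after running a constant-rate linear birth-death process
#' for a duration `dt`: `P(0) = a`, `P(k) = (1-a)(1-b) b^(k-1)` for
#' `k >= 1`, with `a = mu (e^{r dt} - 1) / (lambda e^{r dt} - mu)` and
#' `b = (lambda/mu) a` where r = lambda - mu; in the critical case
#' `lambda = mu` both reduce to `lambda dt / (1 + lambda dt)`.
#'
#' @param lambda speciation rate (> 0).
#' @param mu extinction rate (>= 0).
#' @param dt duration (>= 0). `dt = 0` yields the point mass at one
#'   descendant (`a = 0`, `b = 0`).
#' @return An object of class `zmg` with fields `a` and `b`.
#' @export
zmg_const <- function(lambda, mu, dt) {
  stopifnot(length(lambda) == 1, length(mu) == 1, length(dt) == 1)
  if (!is.finite(dt) || dt < 0) stop("`dt` must be finite and >= 0")
  if (lambda <= 0) stop("`lambda` must be > 0")
  if (mu < 0) stop("`mu` must be >= 0")
  ab <- zmg_const_ab(lambda, mu, dt)
  new_zmg(ab$a, ab$b)
}

#' Compose two ZMG distributions across adjacent time intervals
#'
#' `older` describes descendant counts across the more ancient interval,
#' `younger` across the interval adjacent to the present. Each lineage
#' surviving the older interval seeds an independent copy of the younger
#' distribution; the total is again zero-modified geometric.
#'
#' @param older,younger objects of class `zmg`.
#' @return A `zmg` object.
#' @export
zmg_compose <- function(older, younger) {
  stopifnot(inherits(older, "zmg"), inherits(younger, "zmg"))
  ab <- zmg_compose_ab(older, younger)
  new_zmg(ab$a, ab$b)
}

#' @export
print.zmg <- function(x, ...) {
  cat(sprintf("ZMG(a = %.6g, b = %.6g)  mean = %.6g\n",
              x$a, x$b, (1 - x$a) / (1 - x$b)))
  invisible(x)
}

## log pmf on raw (a, b) vectors; k recycled.
zmg_logpmf_ab <- function(ab, k) {
  n <- max(length(ab$a), length(k))
  a <- rep_len(ab$a, n); b <- rep_len(ab$b, n); k <- rep_len(k, n)
  out <- numeric(n)
  z <- k == 0
  out[z] <- log(a[z])
  if (any(!z)) {
    kk <- k[!z]
    tail_term <- ifelse(kk == 1, 0, (kk - 1) * log(b[!z]))
    out[!z] <- log1p(-a[!z]) + log1p(-b[!z]) + tail_term
  }
  out
}

#' Probability mass of a ZMG distribution
#'
#' @param z a `zmg` object.
#' @param k non-negative integer count(s).
#' @param log return log-probabilities?
#' @return `P(k descendants)` for each `k`.
#' @export
zmg_pmf <- function(z, k, log = FALSE) {
  stopifnot(inherits(z, "zmg"), all(k >= 0), all(k == floor(k)))
  lp <- zmg_logpmf_ab(z, k)
  if (log) lp else exp(lp)
}

## Composed (a, b) of the full skyline process from each age down to the
## present, vectorised over ages. Boundary states at the shift times are
## accumulated once, then each age composes its partial youngest segment.
skyline_zmg_ab <- function(model, ages) {
  if (any(ages < 0)) stop("ages must be >= 0")
  ts <- model$shift_times
  m <- length(ts)
  ## composed ZMG at each boundary t_i (from t_i to present); index i+1
  ba <- numeric(m + 1); bb <- numeric(m + 1) # t_0 = 0 -> identity (0, 0)
  if (m > 0) {
    acc <- list(a = 0, b = 0)
    lo <- c(0, ts)
    for (i in seq_len(m)) {
      seg <- zmg_const_ab(model$lambdas[i], model$mus[i], ts[i] - lo[i])
      acc <- zmg_compose_ab(seg, acc)
      ba[i + 1] <- acc$a; bb[i + 1] <- acc$b
    }
  }
  iv <- interval_index(model, ages)
  t_lo <- c(0, ts)[iv + 1L]
  seg <- zmg_const_ab(model$lambdas[iv + 1L], model$mus[iv + 1L], ages - t_lo)
  zmg_compose_ab(seg, list(a = ba[iv + 1L], b = bb[iv + 1L]))
}

#' Descendant-count distribution under a skyline model
#'
#' `skyline_zmg()` returns the zero-modified-geometric distribution of the
#' number of extant descendants of a lineage alive at age `t`, composing
#' the per-interval distributions across every rate interval between `t`
#' and the present. `pk_skyline()` evaluates its probability mass,
#' the quantity usually written `p_k(t)`.
#'
#' @param model a [skyline_model()].
#' @param t age (>= 0); scalar for `skyline_zmg`, vectorised with `k` for
#'   `pk_skyline`.
#' @param k non-negative descendant count(s).
#' @param log return log-probabilities?
#' @return `skyline_zmg`: a `zmg` object. `pk_skyline`: numeric
#'   probabilities.
#' @examples
#' m <- skyline_model(lambdas = c(0.5, 1), mus = c(0.1, 0.1), shift_times = 2)
#' pk_skyline(m, t = 3, k = 0:5)
#' @export
pk_skyline <- function(model, t, k, log = FALSE) {
  stopifnot(inherits(model, "skyline_model"), all(k >= 0), all(k == floor(k)))
  ab <- skyline_zmg_ab(model, t)
  lp <- zmg_logpmf_ab(ab, k)
  if (log) lp else exp(lp)
}

#' @rdname pk_skyline
#' @export
skyline_zmg <- function(model, t) {
  stopifnot(inherits(model, "skyline_model"), length(t) == 1, t >= 0)
  ab <- skyline_zmg_ab(model, t)
  new_zmg(ab$a, ab$b)
}

#' Survival probability of a lineage
#'
#' Probability that a lineage alive at age `t` has at least one extant
#' descendant at the present, i.e. `1 - p_0(t)`.
#'
#' @inheritParams pk_skyline
#' @return numeric vector of probabilities in (0, 1].
#' @export
p_survival <- function(model, t) {
  stopifnot(inherits(model, "skyline_model"))
  1 - skyline_zmg_ab(model, t)$a
}
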