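## Maximum-likelihood estimation of skyline parameters.
##
## Optimization is over (r_i = lambda_i - mu_i, eps_i = mu_i / lambda_i)
## per interval -- the scale the estimates are reported on -- with bounds
## r in (-10, 10) and eps in [0, 0.999]; parameter combinations implying
## lambda <= 0 get a flat penalty. Shift times are profiled over a
## deterministic grid (hard multi-modal direction), each candidate's rates
## optimized by bounded quasi-Newton from deterministic multistarts, the
## winner polished by one 1-D bounded refinement between its grid
## neighbours.

R_BOUNDS <- c(-10 + 1e-9, 10)
EPS_BOUNDS <- c(0, 0.999)
PENALTY <- -1e10

par_to_rates <- function(par) {
  K <- length(par) / 2L
  r <- par[2 * seq_len(K) - 1L]
  eps <- par[2 * seq_len(K)]
  lam <- r / (1 - eps)
  list(r = r, eps = eps, lambda = lam, mu = lam * eps)
}

hl_objective <- function(hlt, conditioning, shift_times) {
  force(hlt); force(conditioning); force(shift_times)
  function(par) {
    rt <- par_to_rates(par)
    if (any(!is.finite(rt$lambda)) || any(rt$lambda <= 0) || any(rt$mu < 0))
      return(PENALTY)
    ll <- tryCatch(
      loglik_higher_level(hlt, skyline_model(rt$lambda, rt$mu, shift_times),
                          conditioning),
      error = function(e) NA_real_)
    if (!is.finite(ll)) PENALTY else ll
  }
}

## maximize fn over the (r, eps)^K box from the given start matrix
## (one start per row); returns optim-like list or NULL if all starts fail.
## `refine` adds a tight (factr = 100) final polish -- used once per fit,
## not per grid candidate, to keep grid profiling cheap.
maximize_rates <- function(fn, starts, K, maxit = 60L, refine = FALSE) {
  lower <- rep(c(R_BOUNDS[1], EPS_BOUNDS[1]), K)
  upper <- rep(c(R_BOUNDS[2], EPS_BOUNDS[2]), K)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], fn, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(fnscale = -1, maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value <= PENALTY / 2)
      next
    if (fit$value < max(fn(starts[s, ]), PENALTY)) # monotone-improvement guard
      fit <- list(par = starts[s, ], value = fn(starts[s, ]),
                  convergence = 1L)
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (!is.null(best) && refine) {
    ref <- tryCatch(
      optim(best$par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(fnscale = -1, maxit = maxit, factr = 1e2)),
      error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$value) && ref$value >= best$value)
      best <- ref
  }
  best
}

new_fit_result <- function(par, shift_times, logL, n_params, converged,
                           conditioning, grid_trace = NULL) {
  rt <- par_to_rates(par)
  est <- data.frame(interval = seq_along(rt$r) - 1L, r = rt$r, eps = rt$eps,
                    lambda = rt$lambda, mu = rt$mu)
  structure(list(estimates = est, shift_times = shift_times, logL = logL,
                 n_params = n_params, converged = converged,
                 conditioning = conditioning, grid_trace = grid_trace),
            class = "divshift_fit")
}

#' @export
print.divshift_fit <- function(x, ...) {
  cat(sprintf("skyline ML fit: %d interval(s), logL = %.4f%s\n",
              nrow(x$estimates), x$logL,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$shift_times))
    cat("  shift time(s):", paste(format(x$shift_times), collapse = ", "),
        "\n")
  df <- x$estimates
  for (i in seq_len(nrow(df)))
    cat(sprintf("  interval %d (%s): r = %.4f, eps = %.4f\n",
                df$interval[i],
                if (df$interval[i] == 0) "young" else "older",
                df$r[i], df$eps[i]))
  invisible(x)
}

#' Constant-rate maximum-likelihood fit
#'
#' Maximizes the higher-level-tree likelihood over diversification rate
#' r = lambda - mu and turnover `eps = mu / lambda` under a single-rate
#' model, with a bounded quasi-Newton optimizer started from five
#' deterministic points.
#'
#' @param hlt a [higher_level_tree()].
#' @param conditioning as in [loglik_higher_level()].
#' @return a `divshift_fit` with one estimate row (`n_params = 2`). If no
#'   start yields a finite likelihood the fit is flagged not converged
#'   (never an error).
#' @export
fit_constant <- function(hlt, conditioning = "crown_survival") {
  fn <- hl_objective(hlt, conditioning, numeric(0))
  starts <- rbind(c(0.05, 0.3), c(0.2, 0), c(0.5, 0.3), c(1, 0.7), c(2, 0.3))
  best <- maximize_rates(fn, starts, K = 1L, refine = TRUE)
  if (is.null(best))
    return(new_fit_result(c(NA_real_, NA_real_), numeric(0), NA_real_,
                          2L, FALSE, conditioning))
  new_fit_result(best$par, numeric(0), best$value, 2L, TRUE, conditioning)
}

default_shift_grid <- function(hlt, length_out = 20L) {
  x1 <- hlt$branching_times[1]
  seq(hlt$x_cut, 0.9 * x1, length.out = length_out + 1L)[-1L]
}

## one-shift starts derived from a constant fit (r0, e0)
one_shift_starts <- function(r0, e0) {
  rbind(c(r0, e0, r0, e0),
        c(0.5 * r0, e0, 1.5 * r0, e0),
        c(1.5 * r0, e0, 0.5 * r0, e0))
}

#' One-rate-shift maximum-likelihood fit
#'
#' Profiles the shift time over a deterministic grid of candidate ages;
#' at each candidate the four rate parameters (young and old
#' diversification rate and turnover) are optimized, warm-started from
#' the constant fit and from the previous candidate's optimum. The best
#' candidate is refined by one bounded 1-D search between its grid
#' neighbours. Interval 0 is the young (most recent) interval.
#'
#' @param hlt a [higher_level_tree()].
#' @param conditioning as in [loglik_higher_level()].
#' @param grid numeric vector of candidate shift ages, all strictly inside
#'   `(x_cut, x_1)`; default: 20 evenly spaced points between `x_cut` and
#'   `0.9 * x_1`. Candidates outside the valid range are dropped.
#' @param polish refine the winning shift time between its neighbours?
#' @return a `divshift_fit` with two estimate rows, the fitted
#'   `shift_times`, `n_params = 5`, and the profile `grid_trace`
#'   (`data.frame(shift_time, logL)`).
#' @export
fit_one_shift <- function(hlt, conditioning = "crown_survival", grid = NULL,
                          polish = TRUE) {
  x1 <- hlt$branching_times[1]
  if (is.null(grid)) grid <- default_shift_grid(hlt)
  grid <- sort(grid[grid > hlt$x_cut & grid < x1])
  if (!length(grid))
    stop("empty shift-time grid after clipping; candidates must lie in (",
         format(hlt$x_cut), ", ", format(x1), ")")
  cfit <- fit_constant(hlt, conditioning)
  r0 <- if (cfit$converged) cfit$estimates$r[1] else 0.2
  e0 <- if (cfit$converged) cfit$estimates$eps[1] else 0.3
  starts0 <- one_shift_starts(r0, e0)

  trace_ll <- rep(NA_real_, length(grid))
  best <- NULL; best_i <- NA_integer_; prev_par <- NULL
  for (i in seq_along(grid)) {
    fn <- hl_objective(hlt, conditioning, grid[i])
    starts <- if (is.null(prev_par)) starts0 else
      rbind(prev_par, starts0[1, , drop = FALSE])
    opt <- maximize_rates(fn, starts, K = 2L)
    if (is.null(opt)) next
    prev_par <- opt$par
    trace_ll[i] <- opt$value
    if (is.null(best) || opt$value > best$value) {
      best <- opt; best_i <- i
    }
  }
  grid_trace <- data.frame(shift_time = grid, logL = trace_ll)
  if (is.null(best))
    return(new_fit_result(rep(NA_real_, 4), NA_real_, NA_real_, 5L, FALSE,
                          conditioning, grid_trace))
  s_best <- grid[best_i]
  par_best <- best$par; ll_best <- best$value
  if (polish && length(grid) > 1L) {
    lo <- if (best_i > 1L) grid[best_i - 1L] else
      max(hlt$x_cut + 1e-8, 0.5 * grid[1])
    hi <- if (best_i < length(grid)) grid[best_i + 1L] else
      min(x1 - 1e-8, 1.05 * grid[length(grid)])
    prof <- function(s) {
      fn <- hl_objective(hlt, conditioning, s)
      opt <- maximize_rates(fn, rbind(par_best), K = 2L, maxit = 40L)
      if (is.null(opt)) PENALTY else opt$value
    }
    pol <- optimize(prof, lower = lo, upper = hi, maximum = TRUE,
                    tol = max(1e-4, 0.02 * (hi - lo)))
    if (pol$objective > ll_best) {
      s_best <- pol$maximum
      fn <- hl_objective(hlt, conditioning, s_best)
      opt <- maximize_rates(fn, rbind(par_best), K = 2L)
      if (!is.null(opt) && opt$value >= ll_best) {
        par_best <- opt$par; ll_best <- opt$value
      }
    }
  }
  fin <- maximize_rates(hl_objective(hlt, conditioning, s_best),
                        rbind(par_best), K = 2L, refine = TRUE)
  if (!is.null(fin) && fin$value >= ll_best) {
    par_best <- fin$par; ll_best <- fin$value
  }
  new_fit_result(par_best, s_best, ll_best, 5L, TRUE, conditioning,
                 grid_trace)
}

#' Greedy search for multiple rate shifts
#'
#' Adds rate shifts one at a time: the first search fixes nothing, each
#' later search keeps the previously accepted shift times frozen and
#' optimizes all interval rates plus the new candidate shift over the
#' grid. A shift is accepted while the likelihood-ratio test against the
#' previous model has `p < alpha` (3 degrees of freedom per added shift).
#'
#' @param hlt a [higher_level_tree()].
#' @param conditioning as in [loglik_higher_level()].
#' @param max_shifts maximum number of shifts to try (`0` returns the
#'   constant fit only).
#' @param alpha LRT acceptance level.
#' @param grid candidate shift ages (default as in [fit_one_shift()]).
#' @return list with `fits` (constant fit first), `pvalues`, `accepted`
#'   (logical per tried shift), and `best` (last accepted fit).
#' @export
greedy_shift_search <- function(hlt, conditioning = "crown_survival",
                                max_shifts = 1L, alpha = 0.05,
                                grid = NULL) {
  stopifnot(max_shifts >= 0)
  cfit <- fit_constant(hlt, conditioning)
  fits <- list(cfit)
  pvals <- numeric(0); accepted <- logical(0)
  current <- cfit
  fixed <- numeric(0)
  if (max_shifts >= 1L) {
    x1 <- hlt$branching_times[1]
    if (is.null(grid)) grid <- default_shift_grid(hlt)
    for (k in seq_len(max_shifts)) {
      cand <- fit_more_shifts(hlt, conditioning, fixed, grid, current)
      if (is.null(cand)) break
      fits[[length(fits) + 1L]] <- cand
      p <- suppressWarnings(lrt_pvalue(current$logL, cand$logL, df = 3))
      pvals <- c(pvals, p)
      ok <- is.finite(p) && p < alpha
      accepted <- c(accepted, ok)
      if (!ok) break
      current <- cand
      fixed <- sort(cand$shift_times)
    }
  }
  list(fits = fits, pvalues = pvals, accepted = accepted, best = current)
}

## grid search for one additional shift with previous shifts frozen
fit_more_shifts <- function(hlt, conditioning, fixed, grid, current) {
  x1 <- hlt$branching_times[1]
  grid <- grid[grid > hlt$x_cut & grid < x1]
  grid <- grid[!grid %in% fixed]
  if (!length(grid)) return(NULL)
  K <- length(fixed) + 2L
  cur_par <- as.vector(t(as.matrix(current$estimates[, c("r", "eps")])))
  best <- NULL; best_s <- NA_real_
  for (s in grid) {
    shifts <- sort(c(fixed, s))
    ## seed each interval from the nearest interval of the current fit
    old_iv <- findInterval(c(0, shifts), sort(c(0, fixed)),
                           left.open = FALSE)
    start <- as.vector(rbind(cur_par[2 * old_iv - 1L], cur_par[2 * old_iv]))
    fn <- hl_objective(hlt, conditioning, shifts)
    opt <- maximize_rates(fn, rbind(start), K = K)
    if (!is.null(opt) && (is.null(best) || opt$value > best$value)) {
      best <- opt; best_s <- s
    }
  }
  if (is.null(best)) return(NULL)
  new_fit_result(best$par, sort(c(fixed, best_s)), best$value,
                 current$n_params + 3L, TRUE, conditioning)
}

## the six simulation settings: rates youngest-interval-first
STUDY_SETTINGS <- list(
  dec2            = list(lambdas = c(0.5, 1), mus = c(0.1, 0.1), shift = 2),
  dec3.5          = list(lambdas = c(0.5, 1), mus = c(0.1, 0.1), shift = 3.5),
  inc2            = list(lambdas = c(1, 0.5), mus = c(0.1, 0.1), shift = 2),
  inc3.5          = list(lambdas = c(1, 0.5), mus = c(0.1, 0.1), shift = 3.5),
  dec_mu0.4_shift8  = list(lambdas = c(0.5, 1), mus = c(0.4, 0.4), shift = 8),
  dec_mufree_shift2 = list(lambdas = c(1, 1), mus = c(0.6, 0.1), shift = 2))

#' Simulation study: recovery of one rate shift
#'
#' Simulates trees conditioned on `n_tips` extant species under one of six
#' named one-shift scenarios, optionally collapses them at a quantile of
#' the tree age, fits the constant and the one-shift model, and records
#' estimates and the likelihood-ratio test per replicate.
#'
#' @param setting one of `"dec2"`, `"dec3.5"`, `"inc2"`, `"inc3.5"`,
#'   `"dec_mu0.4_shift8"`, `"dec_mufree_shift2"` (decreasing/increasing
#'   diversification; number = shift age).
#' @param n_trees replicates.
#' @param n_tips extant species per simulated tree.
#' @param xcut_quartile 0 for complete trees, else a quantile in (0, 1)
#'   of the tree age at which clades are collapsed.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param grid_length number of shift-time grid candidates per fit.
#' @param out_tsv optional path; the results table is written as TSV.
#' @return `data.frame` with one row per replicate: estimates
#'   (`r_y`, `eps_y`, `r_o`, `eps_o`, `shift_time`), log-likelihoods,
#'   `p_lrt`, sizes and bookkeeping.
#' @export
replicate_study <- function(setting, n_trees = 20, n_tips = 500,
                            xcut_quartile = 0, seed = 1,
                            grid_length = 20L, out_tsv = NULL) {
  setting <- match.arg(setting, names(STUDY_SETTINGS))
  cfg <- STUDY_SETTINGS[[setting]]
  model <- skyline_model(cfg$lambdas, cfg$mus, cfg$shift)
  rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    rep_seed <- seed + i
    tr <- sim_conditioned(model, n_tips, seed = rep_seed)
    if (xcut_quartile > 0) {
      xc <- quartile_xcut(tr, xcut_quartile)
      hlt <- collapse_tree(tr, xc)$hlt
    } else {
      xc <- 0
      sizes <- setNames(rep(1L, n_tips), tr$phy$tip.label)
      hlt <- build_higher_level(tr, sizes, 0)
    }
    f0 <- fit_constant(hlt)
    f1 <- fit_one_shift(hlt, grid = default_shift_grid(hlt, grid_length))
    p <- suppressWarnings(lrt_pvalue(f0$logL, f1$logL, df = 3))
    rows[[i]] <- data.frame(
      replicate = i, setting = setting, xcut = xc, n_tips_hl = hlt$n,
      m = hlt$m,
      r_y = f1$estimates$r[1], eps_y = f1$estimates$eps[1],
      r_o = f1$estimates$r[2], eps_o = f1$estimates$eps[2],
      shift_time = f1$shift_times[1],
      logL0 = f0$logL, logL1 = f1$logL, p_lrt = p, seed = rep_seed)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_tsv))
    write.table(out, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
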