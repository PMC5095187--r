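#' Birth-death-skyline model
#'
#' A birth-death process with piecewise-constant speciation and extinction
#' rates. Time is measured backwards from the present (age 0, increasing
#' into the past). The rate interval boundaries ("shift times")
#' `0 < t_1 < ... < t_m` split time into `m + 1` intervals; interval `i`
#' (0-based) spans ages `(t_i, t_{i+1}]` with `t_0 = 0` and the oldest
#' interval extending to infinity. `lambdas[1]` / `mus[1]` are the rates of
#' the most recent interval.
#'
#' @param lambdas numeric vector of speciation rates, one per interval,
#'   youngest first; all `> 0`.
#' @param mus numeric vector of extinction rates, same length; all `>= 0`.
#' @param shift_times strictly ascending positive ages of the rate shifts;
#'   `length(shift_times) == length(lambdas) - 1`.
#' @return An object of class `skyline_model`.
#' @examples
#' skyline_model(lambdas = c(0.5, 1), mus = c(0.1, 0.1), shift_times = 2)
#' @export
skyline_model <- function(lambdas, mus, shift_times = numeric(0)) {
  lambdas <- as.numeric(lambdas)
  mus <- as.numeric(mus)
  shift_times <- as.numeric(shift_times)
  if (length(lambdas) != length(mus))
    stop("`lambdas` and `mus` must have the same length")
  if (length(lambdas) != length(shift_times) + 1L)
    stop("need length(lambdas) == length(shift_times) + 1 (",
         length(lambdas), " rates for ", length(shift_times), " shifts)")
  if (any(!is.finite(lambdas)) || any(lambdas <= 0))
    stop("speciation rates must be finite and > 0")
  if (any(!is.finite(mus)) || any(mus < 0))
    stop("extinction rates must be finite and >= 0")
  if (length(shift_times) &&
      (any(shift_times <= 0) || any(diff(shift_times) <= 0)))
    stop("`shift_times` must be strictly ascending and positive")
  structure(list(lambdas = lambdas, mus = mus, shift_times = shift_times),
            class = "skyline_model")
}

#' @export
print.skyline_model <- function(x, ...) {
  m <- length(x$shift_times)
  cat("Birth-death-skyline model with", m, "rate shift(s)\n")
  lo <- c(0, x$shift_times)
  hi <- c(x$shift_times, Inf)
  for (i in seq_along(x$lambdas))
    cat(sprintf("  age (%g, %g]: lambda = %g, mu = %g\n",
                lo[i], hi[i], x$lambdas[i], x$mus[i]))
  invisible(x)
}

## 0-based interval index of each age: age in (t_i, t_{i+1}] -> i
interval_index <- function(model, ages) {
  if (!length(model$shift_times)) return(integer(length(ages)))
  findInterval(ages, model$shift_times, left.open = TRUE)
}

#' Rates applying at given ages
#'
#' @param model a [skyline_model()].
#' @param ages numeric vector of ages (backward time, present = 0).
#' @return For `lambda_at` the speciation rate, for `mu_at` the extinction
#'   rate, at each age. An age equal to a shift time `t_i` belongs to the
#'   younger interval `(t_{i-1}, t_i]`.
#' @export
lambda_at <- function(model, ages) model$lambdas[interval_index(model, ages) + 1L]

#' @rdname lambda_at
#' @export
mu_at <- function(model, ages) model$mus[interval_index(model, ages) + 1L]
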