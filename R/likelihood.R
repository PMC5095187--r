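## Log-likelihood of a higher-level phylogeny under a skyline model.
##
## Derivation sketch (all in backward time, present = 0). Write F_{(e,s)}
## for the PGF of the descendant-count ZMG of a lineage from age s down to
## age e, and p_k(t) for the full-process descendant distribution from age
## t to the present. A branch of the observed tree from age s down to age e
## requires the lineage to have, at e, exactly one descendant that goes on
## to be observed while all others leave no sampled descendants; summing
## over the count and which descendant survives gives the branch factor
## F'_{(e,s)}(p_0(e)). The semigroup property of the ZMG family under
## composition yields the telescoping identity
##     F'_{(e,s)}(p_0(e)) = p_1(s) / p_1(e),
## so the product over all branches collapses to factors at the event ages
## only, independent of topology:
##   crown form (root at x_1, n >= 2 tips):
##     L = p_1(x_1)^2 * prod_{i>=2} lambda(x_i) p_1(x_i) * prod_tips c_i
##   stem form (origin at x_0):
##     L = p_1(x_0)   * prod_{i>=1} lambda(x_i) p_1(x_i) * prod_tips c_i
## with per-tip clade factors c_i = p_{n_i}(x_cut) / p_1(x_cut). Because
## p_k is zero-modified geometric, prod_i p_{n_i}(x_cut) depends on the
## clade sizes only through their total m:
##     prod_i p_{n_i}(x_cut) = [(1-a)(1-b)]^n b^(m-n)  at age x_cut,
## which is the partition-invariance property: individual clade sizes are
## irrelevant, only the total species count matters. Both routes are coded
## and must agree. Densities are reported up to a parameter-free constant
## (labelled-tree orientation factor), which cancels from likelihood
## ratios and ML locations.

#' Log-likelihood of a higher-level phylogeny
#'
#' Computes the log of the probability density of a higher-level tree
#' (branching times above `x_cut`, per-tip clade species counts) under a
#' birth-death-skyline model, up to a constant that does not depend on the
#' model parameters.
#'
#' Conditioning: `"crown_survival"` (default) treats the oldest branching
#' `x_1` as the crown age and conditions on both lineages descending from
#' it leaving at least one sampled descendant; `"stem_survival"` requires
#' a stem age and conditions on the stem lineage surviving; `"none"`
#' returns the unconditioned density (stem form when a stem age is
#' recorded, crown form otherwise).
#'
#' Rate intervals older than the root are harmless: the oldest interval
#' extends to infinity, so shift times beyond the stem/root age simply
#' never apply.
#'
#' @param hlt a [higher_level_tree()].
#' @param model a [skyline_model()].
#' @param conditioning one of `"crown_survival"`, `"stem_survival"`,
#'   `"none"`.
#' @param clade_route `"m_only"` uses the total-species-count form of the
#'   clade factors; `"per_tip"` multiplies the individual `p_{n_i}(x_cut)`
#'   factors. The two are mathematically identical (partition invariance)
#'   and kept as mutual regression checks.
#' @return log-density (scalar). `-Inf` for impossible configurations.
#' @examples
#' hlt <- higher_level_tree(c(4, 3), c(5, 3, 2), x_cut = 2)
#' m <- skyline_model(0.6, 0.2)
#' loglik_higher_level(hlt, m)
#' @export
loglik_higher_level <- function(hlt, model,
                                conditioning = c("crown_survival",
                                                 "stem_survival", "none"),
                                clade_route = c("m_only", "per_tip")) {
  stopifnot(inherits(hlt, "higher_level_tree"),
            inherits(model, "skyline_model"))
  conditioning <- match.arg(conditioning)
  clade_route <- match.arg(clade_route)

  x <- hlt$branching_times            # descending, possibly empty
  use_stem <- conditioning == "stem_survival" ||
    (conditioning == "none" && !is.null(hlt$stem_age))
  if (conditioning == "stem_survival" && is.null(hlt$stem_age))
    stop("stem_survival conditioning requires a stem age on the tree")
  if (!use_stem && hlt$n < 2)
    stop("crown form needs >= 2 tips; supply a stem age for n = 1")

  ## composed ZMG state at every age we need, in one vectorised pass
  ages <- c(x, hlt$x_cut, if (use_stem) hlt$stem_age else x[1])
  ab <- skyline_zmg_ab(model, ages)
  nb <- length(x)
  log_p1 <- log1p(-ab$a) + log1p(-ab$b)
  i_cut <- nb + 1L
  i_top <- nb + 2L                     # stem age or (again) crown age

  if (use_stem) {
    ll <- log_p1[i_top] +
      sum(log(lambda_at(model, x))) + sum(log_p1[seq_len(nb)])
    if (conditioning == "stem_survival") ll <- ll - log1p(-ab$a[i_top])
  } else {
    ll <- 2 * log_p1[1] +
      (if (nb >= 2) sum(log(lambda_at(model, x[-1]))) +
         sum(log_p1[2:nb]) else 0)
    if (conditioning == "crown_survival") ll <- ll - 2 * log1p(-ab$a[1])
  }

  ## clade factors at the cut
  a_c <- ab$a[i_cut]; b_c <- ab$b[i_cut]
  if (clade_route == "m_only") {
    extra <- hlt$m - hlt$n
    ll <- ll + if (extra > 0) extra * log(b_c) else 0
  } else {
    lp_tips <- zmg_logpmf_ab(list(a = a_c, b = b_c), hlt$clade_sizes)
    ll <- ll + sum(lp_tips) - hlt$n * (log1p(-a_c) + log1p(-b_c))
  }
  ll
}

#' Log-likelihood of a complete reconstructed tree under a skyline model
#'
#' The species-level special case of [loglik_higher_level()]: cut age 0
#' and one species per tip. Input order of the branching times is
#' irrelevant (set semantics).
#'
#' @param branching_times internal node ages (any order).
#' @param model a [skyline_model()].
#' @param conditioning as in [loglik_higher_level()].
#' @param stem_age optional stem age (required for `"stem_survival"`).
#' @return log-density (scalar, up to a parameter-free constant).
#' @export
loglik_complete_skyline <- function(branching_times, model,
                                    conditioning = c("crown_survival",
                                                     "stem_survival",
                                                     "none"),
                                    stem_age = NULL) {
  if (!length(branching_times)) stop("need at least one branching time")
  hlt <- higher_level_tree(branching_times,
                           rep(1L, length(branching_times) + 1L),
                           x_cut = 0, stem_age = stem_age)
  loglik_higher_level(hlt, model, match.arg(conditioning))
}

#' Likelihood-ratio test p-value for nested skyline models
#'
#' Upper-tail chi-squared p-value of the statistic
#' `2 * (logL_alt - logL_null)`. One added rate shift costs 3 degrees of
#' freedom (speciation rate, extinction rate, shift time); note the
#' shift-time parameter makes the chi-squared reference a convention
#' rather than an exact asymptotic result. A slightly negative statistic
#' (optimizer noise) is clamped to 0 with a warning.
#'
#' @param logL_null,logL_alt maximized log-likelihoods of the nested and
#'   the richer model.
#' @param df degrees of freedom (>= 1); 3 per added shift.
#' @return p-value in (0, 1].
#' @examples
#' lrt_pvalue(-100, -96.1, df = 3)
#' @export
lrt_pvalue <- function(logL_null, logL_alt, df = 3) {
  stopifnot(df >= 1)
  stat <- 2 * (logL_alt - logL_null)
  if (stat < 0) {
    warning("logL_alt < logL_null (", format(stat / 2),
            "); clamping the LRT statistic to 0")
    stat <- 0
  }
  pchisq(stat, df = df, lower.tail = FALSE)
}
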