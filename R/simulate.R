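## Simulation of birth-death-skyline trees and clade collapsing.
##
## Two simulators:
##  * sim_free(): exact forward Gillespie simulation from one lineage at a
##    fixed stem age, returning the complete tree including extinct
##    lineages. Used for Monte-Carlo oracles.
##  * sim_conditioned(): exact sampling of the reconstructed tree
##    conditioned on n extant species. Because rate shifts are ages
##    anchored at the present, the tree is drawn backwards from the
##    present via the inverse-CDF construction: conditioned on the crown
##    (or stem) age, the branching times of a linear birth-death tree are
##    i.i.d. with density lambda(x) p_1(x), whose CDF is b(x) (the
##    geometric parameter of the skyline descendant distribution), and the
##    ranked topology is uniform. The age itself is drawn from its
##    conditional density given n under a uniform prior on the age, which
##    is the distribution the general-sampling-approach stopping rule
##    produces. This is exact, fast, and sidesteps the fixed-point problem
##    of anchoring a forward shift schedule at an as-yet-unknown present.

#' Forward simulation of a birth-death-skyline tree
#'
#' Simulates the complete tree (including extinct lineages) grown from a
#' single lineage at age `x_0`, with exponential waiting times at the
#' per-interval rates of `model`; rates switch at the model's shift times
#' (ages before the present, which is fixed at age 0 = `x_0` time units
#' after the start).
#'
#' @param model a [skyline_model()].
#' @param x_0 stem age (> 0, or 0 for the degenerate single-lineage tree).
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @return a `bd_tree` with extant and extinct tips; attribute
#'   `all_extinct` is `TRUE` when no lineage survived to the present (the
#'   returned tree then contains only extinct tips), and attribute
#'   `stem_age` records `x_0`.
#' @export
sim_free <- function(model, x_0, seed = NULL) {
  stopifnot(inherits(model, "skyline_model"), x_0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  ts <- model$shift_times
  parent <- integer(1); end_age <- numeric(1); died <- logical(1)
  parent[1] <- 0L; end_age[1] <- NA_real_
  nl <- 1L
  alive <- 1L
  age <- x_0
  while (length(alive) && age > 0) {
    iv <- if (length(ts)) findInterval(age, ts, left.open = TRUE) else 0L
    lo <- if (iv > 0) ts[iv] else 0
    lam <- model$lambdas[iv + 1L]; mu <- model$mus[iv + 1L]
    k <- length(alive)
    dt <- stats::rexp(1, k * (lam + mu))
    if (age - dt <= lo) {
      age <- lo # memoryless: re-draw with the next interval's rates
      next
    }
    age <- age - dt
    pick <- sample.int(k, 1)
    j <- alive[pick]
    end_age[j] <- age
    if (runif(1) < lam / (lam + mu)) {
      parent[nl + 1L] <- j; parent[nl + 2L] <- j
      end_age[nl + 1L] <- NA_real_; end_age[nl + 2L] <- NA_real_
      died[nl + 1L] <- FALSE; died[nl + 2L] <- FALSE
      alive <- c(alive[-pick], nl + 1L, nl + 2L)
      nl <- nl + 2L
    } else {
      died[j] <- TRUE
      alive <- alive[-pick]
    }
  }
  end_age[alive] <- 0
  tree <- lineages_to_bd_tree(parent, end_age, died, x_0)
  attr(tree, "stem_age") <- x_0
  tree
}

## Convert a table of lineages (parent id, end age, death flag) into a
## bd_tree. Lineage 1 is the stem; its portion above the first split is
## kept as ape's root.edge.
lineages_to_bd_tree <- function(parent, end_age, died, x_0) {
  nl <- length(parent)
  has_kids <- tabulate(parent, nbins = nl) > 0L
  tip_lin <- which(!has_kids)
  int_lin <- which(has_kids)
  ntip <- length(tip_lin)
  if (ntip == 1L) {
    ## degenerate: the stem never split
    out <- structure(list(phy = NULL, age = end_age[tip_lin],
                          extant = end_age[tip_lin] <= 0,
                          root_age = x_0),
                     class = "bd_tree")
    attr(out, "all_extinct") <- died[tip_lin]
    return(out)
  }
  ## root internal lineage = lineage 1 (its end is the earliest split)
  int_lin <- int_lin[order(end_age[int_lin], decreasing = TRUE)]
  node_id <- integer(nl)
  node_id[tip_lin] <- seq_len(ntip)
  node_id[int_lin] <- ntip + seq_along(int_lin)
  child <- which(parent > 0L)
  edge <- cbind(node_id[parent[child]], node_id[child])
  edge_len <- end_age[parent[child]] - end_age[child]
  labs <- sprintf("t%d", seq_len(ntip))
  phy <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = labs, Nnode = length(int_lin),
                        root.edge = x_0 - end_age[1]),
                   class = "phylo", order = "cladewise")
  ## guard against zero-length edges from simultaneous-looking events
  phy$edge.length <- pmax(phy$edge.length, 1e-12)
  tr <- new_bd_tree(phy)
  ## trust the simulator's own extant flags over the age heuristic
  tr$extant <- end_age[tip_lin] <= 0
  attr(tr, "all_extinct") <- !any(tr$extant)
  tr
}

## log unnormalised density of the crown (or stem) age given n sampled
## tips, under a uniform prior on the age:
##   crown: p^(2)_n(x) = (n - 1) p_1(x)^2 b(x)^(n-2)
##   stem:  p_n(x)     = p_1(x) b(x)^(n-1)
age_logdens <- function(model, x, n, origin) {
  ab <- skyline_zmg_ab(model, x)
  lp1 <- log1p(-ab$a) + log1p(-ab$b)
  lb <- log(ab$b)
  if (origin == "crown") 2 * lp1 + (n - 2) * lb else lp1 + (n - 1) * lb
}

## draw one age from its conditional density by grid inversion
draw_age <- function(model, n, origin) {
  upper <- 1
  repeat {
    grid <- seq(1e-9, upper, length.out = 2048)
    ld <- age_logdens(model, grid, n, origin)
    if (which.max(ld) < 0.9 * length(grid) &&
        ld[length(grid)] < max(ld) - 40) break
    upper <- upper * 2
    if (upper > 1e6) stop("could not bracket the age distribution")
  }
  grid <- seq(1e-9, upper, length.out = 8192)
  ld <- age_logdens(model, grid, n, origin)
  w <- exp(ld - max(ld))
  cdf <- cumsum((w[-1] + w[-length(w)]) / 2 * diff(grid))
  cdf <- c(0, cdf / cdf[length(cdf)])
  approx(cdf, grid, xout = runif(1), ties = "ordered")$y
}

## draw n i.i.d. branching ages on (0, top) with CDF b(x) / b(top)
draw_branching_ages <- function(model, top, n) {
  if (n == 0L) return(numeric(0))
  grid <- seq(0, top, length.out = 8192)
  b <- skyline_zmg_ab(model, grid)$b
  b <- cummax(b) # enforce monotonicity against rounding noise
  u <- runif(n) * b[length(b)]
  approx(b, grid, xout = u, ties = "ordered")$y
}

#' Simulate a reconstructed tree conditioned on the number of extant tips
#'
#' Draws an ultrametric reconstructed tree with exactly `n` extant tips
#' from the birth-death-skyline distribution conditioned on `n` sampled
#' species at the present, with the tree age integrated over a uniform
#' prior (the distribution targeted by general-sampling-approach
#' simulators). Shift times are ages before the present. See the package
#' vignette for the sampling construction.
#'
#' @param model a [skyline_model()].
#' @param n number of extant tips (>= 2).
#' @param seed optional integer seed.
#' @param origin `"crown"` (default): the oldest branching is the root of
#'   the two-lineage crown; `"stem"`: the process starts with one lineage
#'   whose age is drawn too (recorded as attribute `stem_age`).
#' @return an ultrametric `bd_tree` with `n` extant tips.
#' @examples
#' m <- skyline_model(lambdas = c(0.5, 1), mus = c(0.1, 0.1), shift_times = 2)
#' tr <- sim_conditioned(m, n = 50, seed = 1)
#' @export
sim_conditioned <- function(model, n, seed = NULL,
                            origin = c("crown", "stem")) {
  stopifnot(inherits(model, "skyline_model"), n >= 2)
  origin <- match.arg(origin)
  if (!is.null(seed)) set.seed(seed)
  top <- draw_age(model, n, origin)
  if (origin == "crown") {
    ages <- c(top, draw_branching_ages(model, top, n - 2L))
  } else {
    ages <- draw_branching_ages(model, top, n - 1L)
  }
  phy <- ranked_topology(sort(ages), n)
  tr <- new_bd_tree(phy)
  if (origin == "stem") attr(tr, "stem_age") <- top
  tr
}

## Assemble an ultrametric phylo from branching ages (ascending) by
## backward merging with uniformly chosen pairs (uniform ranked topology).
ranked_topology <- function(ages_asc, n) {
  stopifnot(length(ages_asc) == n - 1L)
  nodes_total <- 2L * n - 1L
  edge <- matrix(0L, nodes_total - 1L, 2L)
  edge_len <- numeric(nodes_total - 1L)
  node_age <- c(rep(0, n), rev(ages_asc)) # internal ids oldest-first
  live <- seq_len(n)                      # current lineage -> node id
  next_int <- nodes_total                 # youngest internal gets largest id
  e <- 0L
  for (j in seq_along(ages_asc)) {
    pick <- sample.int(length(live), 2L)
    ch <- live[pick]
    par <- next_int
    next_int <- next_int - 1L
    for (c1 in ch) {
      e <- e + 1L
      edge[e, ] <- c(par, c1)
      edge_len[e] <- node_age[par] - node_age[c1]
    }
    live <- c(live[-pick], par)
  }
  phy <- structure(list(edge = edge, edge.length = pmax(edge_len, 1e-12),
                        tip.label = sprintf("t%d", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Collapse clades at a cut age
#'
#' Turns a reconstructed ultrametric tree into a higher-level phylogeny:
#' every lineage crossing age `x_cut` is collapsed to one representative
#' extant tip (the lexicographically smallest descendant label) carrying
#' the clade's extant species count.
#'
#' @param tree a reconstructed ultrametric `bd_tree`.
#' @param x_cut cut age (>= 0), strictly between branching times; a value
#'   colliding with a branching time is rejected (use [quartile_xcut()]
#'   to nudge).
#' @return list with the collapsed `tree` (a `bd_tree`), the
#'   [higher_level_tree()] `hlt`, and the named clade-size vector `sizes`.
#' @examples
#' tr <- read_newick("((A:3,B:3):1,(C:2,D:2):2);")
#' collapse_tree(tr, x_cut = 2.5)$sizes
#' @export
collapse_tree <- function(tree, x_cut) {
  stopifnot(inherits(tree, "bd_tree"), x_cut >= 0)
  if (!all(tree$extant))
    stop("collapse requires a reconstructed tree (extant tips only)")
  bt <- branching_times(tree)
  tol <- 1e-9 * max(tree$root_age, 1e-300)
  if (any(abs(bt - x_cut) < tol))
    stop("x_cut = ", format(x_cut), " collides with a branching time; ",
         "choose a value strictly inside an inter-branching gap")
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (x_cut < min(bt)) {
    sizes <- setNames(rep(1L, ntip), phy$tip.label)
    hlt <- build_higher_level(tree, sizes, x_cut)
    return(list(tree = tree, hlt = hlt, sizes = sizes))
  }
  ## one postorder pass accumulates, for every node, its descendant tip
  ## count and the lexicographically smallest tip label
  po <- ape::reorder.phylo(phy, "postorder")
  count <- c(rep(1L, ntip), rep(0L, phy$Nnode))
  minlab <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    count[p] <- count[p] + count[ch]
    if (is.na(minlab[p]) || minlab[ch] < minlab[p]) minlab[p] <- minlab[ch]
  }
  ## crossing edges: parent older than the cut, child younger
  pa <- tree$age[phy$edge[, 1]]
  ca <- tree$age[phy$edge[, 2]]
  cross_child <- phy$edge[pa > x_cut & ca < x_cut, 2]
  reps <- minlab[cross_child]
  sizes <- count[cross_child]
  keep <- ape::keep.tip(phy, reps)
  ctree <- new_bd_tree(keep)
  sizes <- setNames(sizes, reps)[ctree$phy$tip.label]
  hlt <- build_higher_level(ctree, sizes, x_cut)
  list(tree = ctree, hlt = hlt, sizes = sizes)
}

#' Cut age at a quantile of the tree age
#'
#' Returns `q * root_age`; if that collides with a branching time it is
#' nudged toward the present, to the midpoint between the colliding
#' branching time and the next younger one (or the present), keeping the
#' cut strictly inside an inter-branching gap.
#'
#' @param tree a reconstructed `bd_tree`.
#' @param q quantile in (0, 1), e.g. 0.25, 0.5, 0.75.
#' @return a valid cut age.
#' @export
quartile_xcut <- function(tree, q) {
  stopifnot(inherits(tree, "bd_tree"), q > 0, q < 1)
  x <- q * tree$root_age
  bt <- branching_times(tree)
  tol <- 1e-9 * max(tree$root_age, 1e-300)
  hit <- which(abs(bt - x) < tol)
  if (length(hit)) {
    below <- bt[bt < bt[hit[1]] - tol]
    lower <- if (length(below)) max(below) else 0
    x <- (lower + bt[hit[1]]) / 2
  }
  x
}
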