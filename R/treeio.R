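## Timetree I/O and the higher-level tree container.
##
## Newick parsing/writing is delegated to ape; this module adds node ages
## in backward time (present = 0), extant/extinct flags, and validation.
## Clade sizes travel in a sidecar TSV ("tip<TAB>n_species") so the newick
## stays standard-compliant.

## Relative tolerance below which a tip age counts as 0 (extant).
ULTRAMETRIC_RTOL <- 1e-6

new_bd_tree <- function(phy) {
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; durations are required on every edge")
  if (any(phy$edge.length <= 0))
    stop("all edge durations must be > 0")
  ntip <- length(phy$tip.label)
  kids <- tabulate(phy$edge[, 1], nbins = ntip + phy$Nnode)
  bad <- which(kids[(ntip + 1L):(ntip + phy$Nnode)] != 2L)
  if (length(bad))
    stop("tree is not binary: internal node ", ntip + bad[1], " has ",
         kids[ntip + bad[1]], " children")
  depth <- ape::node.depth.edgelength(phy)  # root-to-node path lengths
  age <- max(depth[seq_len(ntip)]) - depth
  root_age <- age[ntip + 1L]
  extant <- age[seq_len(ntip)] <= ULTRAMETRIC_RTOL * max(root_age, 1e-300)
  structure(list(phy = phy, age = age, extant = extant, root_age = root_age),
            class = "bd_tree")
}

#' Read a newick timetree
#'
#' Parses a rooted binary newick tree with branch lengths and derives node
#' ages in backward time: the present (age 0) is the tip furthest from the
#' root, and every node's age is that maximum depth minus its own depth.
#' Tips whose age is within `1e-6` of the root age (relative) are flagged
#' extant, all others extinct.
#'
#' @param text newick string.
#' @param file path to a newick file (alternative to `text`).
#' @return An object of class `bd_tree`: a list with the `ape::phylo` tree
#'   (`$phy`), node ages (`$age`, tips first in ape's node numbering), the
#'   per-tip extant flag (`$extant`) and `$root_age`.
#' @examples
#' tr <- read_newick("((A:3,B:3):1,(C:2,D:2):2);")
#' branching_times(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  phy <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("malformed newick input")
  ## a single-child root (e.g. "((A:1,B:2):1);") encodes a stem edge
  phy <- ape::collapse.singles(phy, root.edge = TRUE)
  new_bd_tree(phy)
}

#' @rdname read_newick
#' @param tree a `bd_tree`.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "bd_tree"))
  s <- ape::write.tree(tree$phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @export
print.bd_tree <- function(x, ...) {
  cat(sprintf("timetree: %d tips (%d extant), root age %.6g\n",
              length(x$extant), sum(x$extant), x$root_age))
  invisible(x)
}

#' Branching times of a reconstructed tree
#'
#' Ages of all internal nodes, sorted descending (oldest first). The tree
#' must be reconstructed, i.e. contain extant tips only; prune extinct
#' lineages first (see [reconstructed()]). Tied ages are ordered by ape
#' node number (cladewise order), a stable, documented tie-break.
#'
#' @param tree a `bd_tree`.
#' @return numeric vector of `n_tips - 1` ages, descending.
#' @export
branching_times <- function(tree) {
  stopifnot(inherits(tree, "bd_tree"))
  if (!all(tree$extant))
    stop("tree has extinct tips; prune them first (see `reconstructed()`)")
  ntip <- length(tree$extant)
  ages <- tree$age[(ntip + 1L):length(tree$age)]
  ages[order(-ages)]
}

#' Prune extinct lineages
#'
#' Returns the reconstructed tree: all tips not flagged extant are dropped
#' (with their pendant lineages) and degree-two nodes are fused.
#'
#' @param tree a `bd_tree`.
#' @return a `bd_tree` with extant tips only.
#' @export
reconstructed <- function(tree) {
  stopifnot(inherits(tree, "bd_tree"))
  if (all(tree$extant)) return(tree)
  if (sum(tree$extant) < 2)
    stop("fewer than 2 extant tips; reconstructed tree is degenerate")
  phy <- ape::drop.tip(tree$phy, which(!tree$extant))
  new_bd_tree(phy)
}

#' Read / write the clade-size sidecar table
#'
#' Two tab-separated columns with header `tip<TAB>n_species`; lines
#' starting with `#` (e.g. a provenance header) are ignored.
#'
#' @param file path to a TSV file.
#' @param text TSV content as a string (alternative to `file`).
#' @return named integer vector mapping tip label to species count.
#' @export
read_clade_sizes <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  df <- if (is.null(file))
    read.delim(text = text, comment.char = "#", stringsAsFactors = FALSE)
  else
    read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!identical(names(df), c("tip", "n_species")))
    stop('clade-size table must have header "tip\\tn_species"')
  if (anyDuplicated(df$tip))
    stop("duplicate tip label(s): ",
         paste(unique(df$tip[duplicated(df$tip)]), collapse = ", "))
  n <- suppressWarnings(as.numeric(df$n_species))
  if (any(is.na(n)) || any(n != floor(n)))
    stop("species counts must be integers")
  if (any(n < 1)) stop("species counts must be >= 1")
  setNames(as.integer(n), df$tip)
}

#' @rdname read_clade_sizes
#' @param sizes named integer vector (tip label -> count).
#' @param header optional comment line(s) written verbatim before the table
#'   (each prefixed with `#` if not already).
#' @export
write_clade_sizes <- function(sizes, file, header = NULL) {
  stopifnot(is.numeric(sizes), !is.null(names(sizes)))
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    header <- ifelse(startsWith(header, "#"), header, paste0("# ", header))
    writeLines(header, con)
  }
  writeLines("tip\tn_species", con)
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), con)
  invisible(file)
}

#' Higher-level tree
#'
#' The sufficient data of a higher-level phylogeny: the branching times
#' `x_1 > ... > x_{n-1}` of the tree resolved above the cut age `x_cut`,
#' and for each of the `n` tips the number of extant species `n_i` in the
#' clade it represents (total `m = sum(n_i)`). An optional stem age
#' `x_0 > x_1` may be recorded.
#'
#' @param branching_times ages of the internal nodes (any order; stored
#'   descending); all must exceed `x_cut`.
#' @param clade_sizes integer species counts, one per tip, each `>= 1`.
#'   `length(clade_sizes) == length(branching_times) + 1`.
#' @param x_cut cut age `>= 0`. `x_cut = 0` with unit clade sizes is a
#'   complete species-level tree.
#' @param stem_age optional stem age, older than all branching times.
#' @return object of class `higher_level_tree` with fields
#'   `branching_times`, `clade_sizes`, `x_cut`, `m`, `n`, `stem_age`.
#' @export
higher_level_tree <- function(branching_times, clade_sizes, x_cut = 0,
                              stem_age = NULL) {
  branching_times <- sort(as.numeric(branching_times), decreasing = TRUE)
  clade_sizes <- as.numeric(clade_sizes)
  if (any(clade_sizes < 1) || any(clade_sizes != floor(clade_sizes)))
    stop("clade sizes must be integers >= 1")
  n <- length(clade_sizes)
  if (length(branching_times) != n - 1L)
    stop("need one more clade size than branching times (n tips, n-1 nodes)")
  if (!is.finite(x_cut) || x_cut < 0) stop("`x_cut` must be >= 0")
  if (length(branching_times) && min(branching_times) <= x_cut)
    stop("all branching times must be > x_cut (oldest violation at age ",
         format(min(branching_times)), ")")
  if (!is.null(stem_age)) {
    ## strict vs branching times; equality with x_cut allowed (a clade cut
    ## directly at its stem is the degenerate one-tip case)
    if (length(branching_times) && stem_age <= branching_times[1])
      stop("`stem_age` must be older than every branching time")
    if (stem_age < x_cut) stop("`stem_age` must be >= x_cut")
  }
  structure(list(branching_times = branching_times,
                 clade_sizes = as.integer(clade_sizes),
                 x_cut = as.numeric(x_cut), n = n,
                 m = as.integer(sum(clade_sizes)),
                 stem_age = stem_age),
            class = "higher_level_tree")
}

#' @export
print.higher_level_tree <- function(x, ...) {
  cat(sprintf("higher-level tree: %d tips, %d species, x_cut = %.6g\n",
              x$n, x$m, x$x_cut))
  if (length(x$branching_times))
    cat("  root age:", format(x$branching_times[1]), "\n")
  if (!is.null(x$stem_age)) cat("  stem age:", format(x$stem_age), "\n")
  invisible(x)
}

#' Build a higher-level tree from a timetree and clade sizes
#'
#' Validates that `tree` is reconstructed (extant tips only), ultrametric,
#' fully resolved above `x_cut` (every branching older than the cut), and
#' that every tip has a species count; then assembles the
#' [higher_level_tree()].
#'
#' @param tree a reconstructed `bd_tree`.
#' @param sizes named integer vector (tip label -> species count).
#' @param x_cut cut age.
#' @param stem_age optional stem age.
#' @return a `higher_level_tree`.
#' @export
build_higher_level <- function(tree, sizes, x_cut, stem_age = NULL) {
  stopifnot(inherits(tree, "bd_tree"))
  if (!all(tree$extant))
    stop("tree has extinct tips; a higher-level tree is built from a ",
         "reconstructed tree")
  labs <- tree$phy$tip.label
  missing <- setdiff(labs, names(sizes))
  if (length(missing))
    stop("no species count for tip(s): ", paste(missing, collapse = ", "))
  bt <- branching_times(tree)
  if (min(bt) <= x_cut)
    stop("branching time at age ", format(min(bt)), " is <= x_cut = ",
         format(x_cut), "; the tree is not fully resolved above the cut")
  higher_level_tree(bt, sizes[labs], x_cut, stem_age)
}
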