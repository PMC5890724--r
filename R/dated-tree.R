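#' Construct a dated tree
#'
#' Wraps an `ape::phylo` topology whose branch lengths are durations in Ma,
#' together with node ages (Ma before a reference, larger = older; fossil
#' tips may have age > 0) and an optional parallel set of per-branch
#' character lengths (expected substitutions per character) used for
#' simulation and likelihoods.
#'
#' @param phy rooted binary `phylo` with positive `edge.length` (durations, Ma).
#' @param tip_ages named numeric vector of tip ages (Ma); unnamed scalar 0
#'   means all tips extant-equivalent.  Internal ages are propagated from the
#'   tips; two paths implying ages differing by more than `tol` is an error.
#' @param char_lengths optional numeric vector, one per edge (in
#'   `phy$edge` order), expected substitutions per character.
#' @param tol age-consistency tolerance (Ma).
#' @return object of class `dated_tree`: list with `phy`, `ages` (length
#'   Ntip + Nnode, ape node numbering), `char_lengths` (or `NULL`).
#' @export
dated_tree <- function(phy, tip_ages = 0, char_lengths = NULL, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree needs branch lengths (durations)")
  if (any(phy$edge.length <= 0))
    stop("all branch durations must be > 0 (zero/negative length found)")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("tree must be rooted and binary")
  ntip <- length(phy$tip.label)
  if (length(tip_ages) == 1L && is.null(names(tip_ages)))
    tip_ages <- stats::setNames(rep(tip_ages, ntip), phy$tip.label)
  miss <- setdiff(phy$tip.label, names(tip_ages))
  if (length(miss))
    stop("tip label(s) absent from date table: ", paste(miss, collapse = ", "))
  if (any(tip_ages[phy$tip.label] < 0)) stop("tip ages must be >= 0")
  ages <- numeric(ntip + phy$Nnode)
  ages[] <- NA_real_
  ages[seq_len(ntip)] <- as.numeric(tip_ages[phy$tip.label])
  po <- ape::postorder(phy)
  for (e in po) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    cand <- ages[ch] + phy$edge.length[e]
    if (is.na(ages[p])) ages[p] <- cand
    else if (abs(ages[p] - cand) > tol)
      stop(sprintf("inconsistent node ages: node %d implied %.6f and %.6f",
                   p, ages[p], cand))
  }
  if (!is.null(char_lengths)) {
    if (length(char_lengths) != nrow(phy$edge))
      stop("char_lengths must have one entry per branch")
    if (any(char_lengths < 0)) stop("char_lengths must be >= 0")
  }
  structure(list(phy = phy, ages = ages, char_lengths = char_lengths),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("<dated_tree> %d tips, root age %.4f Ma, %s character lengths\n",
              length(x$phy$tip.label), root_age(x),
              if (is.null(x$char_lengths)) "no" else "with"))
  invisible(x)
}

#' Branch durations of a dated tree (Ma, in edge order)
#' @param x a [dated_tree].
#' @export
durations <- function(x) x$phy$edge.length

#' Tip ages of a dated tree (named, Ma)
#' @param x a [dated_tree].
#' @export
tip_ages <- function(x)
  stats::setNames(x$ages[seq_along(x$phy$tip.label)], x$phy$tip.label)

#' Root age of a dated tree (Ma)
#' @param x a [dated_tree].
#' @export
root_age <- function(x) x$ages[length(x$phy$tip.label) + 1L]

# durations recomputed from ages; invariant check used throughout the tests
ages_to_durations <- function(phy, ages)
  ages[phy$edge[, 1]] - ages[phy$edge[, 2]]

# rebuild a dated_tree from new internal ages (tips fixed); used by the MCMC
set_internal_ages <- function(x, internal_ages) {
  ntip <- length(x$phy$tip.label)
  ages <- x$ages
  ages[(ntip + 1L):length(ages)] <- internal_ages
  phy <- x$phy
  phy$edge.length <- ages_to_durations(phy, ages)
  structure(list(phy = phy, ages = ages, char_lengths = x$char_lengths),
            class = "dated_tree")
}

#' Read a dated tree from newick plus a tip-date table
#'
#' Branch lengths in the newick are durations in Ma; node ages are assigned
#' so every tip matches its table entry and internal ages propagate as
#' child age + child branch duration, with consistency checked across the
#' two paths into every internal node.
#'
#' @param newick path to a newick file.
#' @param dates named numeric vector of tip ages (see [read_tip_dates()]).
#' @return a [dated_tree].
#' @export
read_dated_tree <- function(newick, dates) {
  phy <- ape::read.tree(newick)
  if (is.null(phy)) stop("could not read newick: ", newick)
  dated_tree(phy, tip_ages = dates)
}

#' Write a dated tree as newick (durations as branch lengths)
#' @param x a [dated_tree].
#' @param path output path.
#' @export
write_dated_tree <- function(x, path) {
  ape::write.tree(x$phy, file = path, digits = 12)
  invisible(path)
}
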