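# shared fixtures and independent oracles (brute force, enumeration)

# a dated tree with heterochronous tips derived from a random topology:
# rtree branch lengths are taken as durations and tip ages fall out of the
# node depths
random_dated_tree <- function(n, seed, min_len = 0.1, max_len = 2) {
  set.seed(seed)
  phy <- ape::rtree(n)
  phy$edge.length <- stats::runif(nrow(phy$edge), min_len, max_len)
  depth <- numeric(n + phy$Nnode)
  for (e in rev(ape::postorder(phy)))
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  ages <- max(depth[seq_len(n)]) - depth[seq_len(n)]
  dated_tree(phy, tip_ages = stats::setNames(ages, phy$tip.label))
}

# exact Mk likelihood by summation over every internal-node state
# assignment (and over states of missing tips)
brute_force_lik <- function(tree, column, k) {
  phy <- tree$phy
  v <- tree$char_lengths
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (!is.null(names(column))) column <- column[phy$tip.label]
  P <- lapply(seq_len(nrow(phy$edge)),
              function(e) mk_transition_matrix(k, v[e]))
  free <- c(which(is.na(column)), ntip + seq_len(nnode))  # tips NA + internals
  fixed <- stats::setNames(column, seq_len(ntip))
  grid <- do.call(expand.grid, rep(list(0:(k - 1)), length(free)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + nnode)
    st[seq_len(ntip)] <- column
    st[free] <- as.integer(grid[g, ])
    p <- 1 / k
    for (e in seq_len(nrow(phy$edge)))
      p <- p * P[[e]][st[phy$edge[e, 1]] + 1L, st[phy$edge[e, 2]] + 1L]
    total <- total + p
  }
  total
}

# minimum parsimony steps by enumeration of internal-node assignments
brute_force_steps <- function(phy, column, k) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (!is.null(names(column))) column <- column[phy$tip.label]
  free <- c(which(is.na(column)), ntip + seq_len(nnode))
  grid <- do.call(expand.grid, rep(list(0:(k - 1)), length(free)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + nnode)
    st[seq_len(ntip)] <- column
    st[free] <- as.integer(grid[g, ])
    steps <- sum(st[phy$edge[, 1]] != st[phy$edge[, 2]])
    best <- min(best, steps)
  }
  best
}

# all k^n site patterns as a matrix, one row per pattern
all_patterns <- function(n, k) {
  pat <- as.matrix(expand.grid(rep(list(0:(k - 1)), n)))
  dimnames(pat) <- NULL
  pat
}

is_parsimony_informative <- function(pattern, k) {
  counts <- tabulate(pattern + 1L, nbins = k)
  sum(counts >= 2L) >= 2L
}

# 4 taxa x 6 characters: 2 invariant, 2 autapomorphic, 2 informative
toy_matrix <- function() {
  states <- rbind(
    t1 = c(0L, 1L, 0L, 1L, 0L, 1L),
    t2 = c(0L, 1L, 0L, 0L, 0L, 0L),
    t3 = c(0L, 1L, 0L, 0L, 1L, 1L),
    t4 = c(0L, 1L, 1L, 0L, 1L, 0L))
  char_matrix(states, n_states = 2L)
}
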