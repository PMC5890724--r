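#' Birth-death serial-sampling parameters
#'
#' Parameters of the forward birth-death process with Poissonian sampling
#' through time: each lineage branches at rate `lambda`, goes extinct at
#' rate `mu`, and is sampled (and removed, becoming a dated fossil tip) at
#' rate `psi`, all per lineage per Ma.  `lambda > mu + psi` is required for
#' the sampled-tip count to grow.
#'
#' @param lambda birth rate (> 0).
#' @param mu death rate (>= 0).
#' @param psi serial sampling rate (> 0: fossil tips are the point).
#' @param n_tips target number of sampled tips.
#' @param time_cap abort a replicate exceeding this time span (Ma).
#' @return object of class `bdss_params`.
#' @export
bdss_params <- function(lambda = 1.5, mu = 0.3, psi = 0.8,
                        n_tips = 30, time_cap = 1000) {
  stopifnot(lambda > 0, mu >= 0, psi > 0, n_tips >= 2, time_cap > 0)
  structure(list(lambda = lambda, mu = mu, psi = psi,
                 n_tips = as.integer(n_tips), time_cap = time_cap),
            class = "bdss_params")
}

# one forward realisation; returns node table or NULL on failure
bdss_forward <- function(p) {
  max_nodes <- 200000L
  parent <- integer(max_nodes); time <- numeric(max_nodes)
  type <- integer(max_nodes)  # 0 origin, 1 birth, 2 death, 3 sample
  parent[1] <- 0L; time[1] <- 0; type[1] <- 0L
  n_nodes <- 1L
  active <- 1L          # origin node ids each active lineage descends from
  n_samp <- 0L
  t <- 0
  rate1 <- p$lambda + p$mu + p$psi
  repeat {
    n_act <- length(active)
    if (n_act == 0L) return(NULL)                       # extinct too early
    t <- t + stats::rexp(1, n_act * rate1)
    if (t > p$time_cap || n_nodes + 2L > max_nodes) return(NULL)
    i <- if (n_act == 1L) 1L else sample.int(n_act, 1L)
    ev <- sample.int(3L, 1L, prob = c(p$lambda, p$mu, p$psi))
    n_nodes <- n_nodes + 1L
    parent[n_nodes] <- active[i]; time[n_nodes] <- t; type[n_nodes] <- ev
    if (ev == 1L) {                                     # birth: split
      active <- c(active[-i], n_nodes, n_nodes)
    } else {                                            # death or sample
      active <- active[-i]
      if (ev == 3L) {
        n_samp <- n_samp + 1L
        if (n_samp == p$n_tips)
          return(list(parent = parent[1:n_nodes], time = time[1:n_nodes],
                      type = type[1:n_nodes]))
      }
    }
  }
}

# prune the full event tree to the genealogy of the sampled tips and
# convert to an ape phylo with durations as branch lengths
bdss_prune <- function(ev, n_tips) {
  n <- length(ev$parent)
  cnt <- as.integer(ev$type == 3L)            # sampled descendants per node
  for (id in n:2) cnt[ev$parent[id]] <- cnt[ev$parent[id]] + cnt[id]
  kept_children <- vector("list", n)
  for (id in 2:n) if (cnt[id] > 0L)
    kept_children[[ev$parent[id]]] <- c(kept_children[[ev$parent[id]]], id)
  resolve <- function(id) {                   # skip single-child chains
    repeat {
      if (ev$type[id] == 3L) return(id)
      kc <- kept_children[[id]]
      if (length(kc) == 2L) return(id)
      id <- kc[1]
    }
  }
  mrca <- resolve(1L)
  edges_from <- integer(0); edges_to <- integer(0)
  stack <- mrca
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in kept_children[[nd]]) {
      r <- resolve(ch)
      edges_from <- c(edges_from, nd); edges_to <- c(edges_to, r)
      if (ev$type[r] != 3L) stack <- c(stack, r)
    }
  }
  tips <- edges_to[ev$type[edges_to] == 3L]
  tips <- tips[order(ev$time[tips])]          # t1 = oldest sample
  internals <- unique(c(mrca, edges_from))
  new_id <- integer(n)
  new_id[tips] <- seq_along(tips)
  new_id[mrca] <- n_tips + 1L
  rest <- setdiff(internals, mrca)
  new_id[rest] <- n_tips + 1L + seq_along(rest)
  edge <- cbind(new_id[edges_from], new_id[edges_to])
  phy <- structure(list(
    edge = edge,
    edge.length = ev$time[edges_to] - ev$time[edges_from],
    tip.label = paste0("t", seq_len(n_tips)),
    Nnode = n_tips - 1L), class = "phylo")
  t_ref <- max(ev$time[tips])
  ages <- stats::setNames(t_ref - ev$time[tips], phy$tip.label)
  list(phy = phy, tip_ages = ages)
}

#' Simulate a dated tree under birth-death serial sampling
#'
#' Forward Gillespie simulation of the BDSS process; sampling removes the
#' lineage (no sampled ancestors), so the `n_tips` sampled fossils become
#' dated terminal taxa.  The realisation is conditioned on reaching exactly
#' `n_tips` samples by rejection; the pruned genealogy of the samples is
#' returned with ages in Ma before the youngest tip.
#'
#' @param params a [bdss_params].
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling attempt cap.
#' @return a [dated_tree]; attribute `"attempts"` records the rejections.
#' @export
simulate_bdss_tree <- function(params, seed, max_attempts = 10000) {
  stopifnot(inherits(params, "bdss_params"))
  set.seed(seed)
  for (att in seq_len(max_attempts)) {
    ev <- bdss_forward(params)
    if (!is.null(ev)) {
      pr <- bdss_prune(ev, params$n_tips)
      out <- dated_tree(pr$phy, tip_ages = pr$tip_ages)
      attr(out, "attempts") <- att
      return(out)
    }
  }
  stop("could not reach ", params$n_tips, " sampled tips in ", max_attempts,
       " attempts; increase lambda or psi relative to mu")
}

#' Permute branch durations into non-clock character lengths
#'
#' Produces the non-clock simulation condition: the time tree (topology,
#' node ages, tip dates) is untouched, but the per-branch lengths used for
#' character simulation become a uniform random permutation of the branch
#' durations, destroying the correlation between elapsed time and expected
#' character change.
#'
#' @param tree a [dated_tree].
#' @param seed RNG seed.
#' @return the tree with `char_lengths` set to the permuted durations (Ma;
#'   multiply by a rate before simulating characters).
#' @export
reshuffle_branch_lengths <- function(tree, seed) {
  stopifnot(inherits(tree, "dated_tree"))
  set.seed(seed)
  tree$char_lengths <- sample(durations(tree))
  tree
}

#' Build the clock / non-clock benchmark dataset
#'
#' Emulates the study conditions: one BDSS tree, a "strict clock" matrix
#' simulated on branch durations times a low per-Ma rate (so a large share
#' of characters come out invariant or autapomorphic), a "non-clock" matrix
#' simulated on reshuffled branch lengths at the same rate, and the
#' ascertainment-filtered (variable-only, parsimony-informative-only)
#' variants of both.
#'
#' @param params a [bdss_params] (default 30 tips).
#' @param rate clock rate, substitutions/character/Ma (default 0.05).
#' @param n_chars characters per condition (default 1000).
#' @param k number of states (default 2, binary).
#' @param seed master seed; component seeds are derived from it.
#' @return object of class `synthetic_dataset`: list with `tree`,
#'   `reshuffled_lengths`, `clock` and `nonclock` (each a list `full`,
#'   `variable_only`, `parsinf_only` of [char_matrix]), `manifest`.
#' @export
make_benchmark <- function(params = bdss_params(), rate = 0.05,
                           n_chars = 1000, k = 2, seed = 1) {
  seeds <- list(tree = seed, reshuffle = seed + 1L,
                clock = seed + 2L, nonclock = seed + 3L)
  tree <- simulate_bdss_tree(params, seeds$tree)
  clock_tree <- tree
  clock_tree$char_lengths <- durations(tree) * rate
  m_clock <- simulate_characters(clock_tree, k, n_chars, seeds$clock)
  rs <- reshuffle_branch_lengths(tree, seeds$reshuffle)
  nonclock_tree <- rs
  nonclock_tree$char_lengths <- rs$char_lengths * rate
  m_nonclock <- simulate_characters(nonclock_tree, k, n_chars, seeds$nonclock)
  p_clock <- partition_matrix(m_clock)
  p_nonclock <- partition_matrix(m_nonclock)
  frac_ia <- function(p) sum(p$counts[c("invariant", "autapomorphic")]) /
    max(1, sum(p$counts))
  manifest <- list(
    params = unclass(params), rate = rate, n_chars = n_chars, k = k,
    seeds = seeds,
    class_counts = list(clock = as.list(p_clock$counts),
                        nonclock = as.list(p_nonclock$counts)),
    frac_invariant_autapomorphic = list(clock = frac_ia(p_clock),
                                        nonclock = frac_ia(p_nonclock)),
    bdss_attempts = attr(tree, "attempts"))
  structure(list(
    tree = tree,
    reshuffled_lengths = rs$char_lengths,
    clock = list(full = m_clock, variable_only = p_clock$variable_only,
                 parsinf_only = p_clock$parsinf_only),
    nonclock = list(full = m_nonclock,
                    variable_only = p_nonclock$variable_only,
                    parsinf_only = p_nonclock$parsinf_only),
    manifest = manifest), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d tips, %d chars, rate %.3g; invariant+autapomorphic: clock %.2f, nonclock %.2f\n",
    length(x$tree$phy$tip.label), x$manifest$n_chars, x$manifest$rate,
    x$manifest$frac_invariant_autapomorphic$clock,
    x$manifest$frac_invariant_autapomorphic$nonclock))
  invisible(x)
}

#' Write a benchmark dataset to disk
#'
#' NEXUS matrices (both conditions, all three filterings), the newick tree,
#' the CSV tip-date table and a JSON manifest.
#'
#' @param x a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_synthetic_dataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in c("clock", "nonclock"))
    for (filt in c("full", "variable_only", "parsinf_only"))
      write_nexus_matrix(x[[cond]][[filt]],
                         file.path(dir, paste0(cond, "_", filt, ".nex")))
  write_dated_tree(x$tree, file.path(dir, "tree.nwk"))
  write_tip_dates(tip_ages(x$tree), file.path(dir, "tip_dates.csv"))
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
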