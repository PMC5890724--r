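#' Site-model configuration
#'
#' Chooses among the plain Mk likelihood and its two ascertainment-bias
#' corrections: `mkv` conditions on characters being variable (invariant
#' patterns unobservable), `mkparsinf` conditions on characters being
#' parsimony informative (all uninformative patterns unobservable).  Branch
#' lengths are always expected substitutions per character.
#'
#' @param model `"mk"`, `"mkv"` or `"mkparsinf"`.
#' @param k number of states (>= 2 for likelihood use).
#' @return object of class `site_model`.
#' @export
site_model <- function(model = c("mk", "mkv", "mkparsinf"), k = 2L) {
  model <- match.arg(model)
  stopifnot(k >= 2)
  structure(list(model = model, k = as.integer(k)), class = "site_model")
}

#' Mk transition probability matrix
#'
#' Closed form for the symmetric k-state Markov model with total leaving
#' rate 1, so `v` is the expected number of substitutions:
#' `P_same = 1/k + (k-1)/k * exp(-v k/(k-1))`,
#' `P_diff = 1/k - 1/k * exp(-v k/(k-1))`.
#'
#' @param k number of states (>= 2).
#' @param v branch length, expected substitutions per character (>= 0).
#' @return `k x k` row-stochastic matrix.
#' @export
mk_transition_matrix <- function(k, v) {
  stopifnot(k >= 2)
  if (v < 0) stop("branch length must be >= 0")
  ex <- exp(-v * k / (k - 1))
  p_same <- 1 / k + (k - 1) / k * ex
  p_diff <- 1 / k - 1 / k * ex
  m <- matrix(p_diff, k, k)
  diag(m) <- p_same
  m
}

# branch lengths in expected substitutions for likelihood work
char_branch_lengths <- function(tree) {
  if (is.null(tree$char_lengths))
    stop("tree has no char_lengths; set them or supply a rate")
  tree$char_lengths
}

# batch pruning over a tip x pattern matrix (rows in tree tip order)
pattern_likelihoods <- function(tree, patterns, k) {
  phy <- tree$phy
  mk_pattern_lik(phy$edge, char_branch_lengths(tree), ape::postorder(phy),
                 length(phy$tip.label), phy$Nnode,
                 patterns, as.integer(k))
}

#' Pruning likelihood of one character column
#'
#' Exact Mk likelihood of a site pattern on a dated tree via Felsenstein's
#' pruning algorithm, with uniform root state frequencies `1/k`.  Missing
#' tips contribute all-ones partials.  Branch lengths are the tree's
#' `char_lengths` (expected substitutions).
#'
#' @param tree a [dated_tree] with `char_lengths` set.
#' @param column integer states (`NA` = missing), named by taxon or in tree
#'   tip order.
#' @param k number of states.
#' @return the pattern likelihood (probability).
#' @export
pruning_likelihood <- function(tree, column, k) {
  tips <- tree$phy$tip.label
  if (!is.null(names(column))) {
    if (!setequal(names(column), tips))
      stop("column names do not match tree tips")
    column <- column[tips]
  } else if (length(column) != length(tips))
    stop("column length does not match number of tips")
  pattern_likelihoods(tree, matrix(as.integer(column), ncol = 1), k)[1]
}

# representative pattern + multiplicity per symmetry class of the
# uninformative set.  Under Mk with uniform roots the likelihood of a
# pattern depends only on which taxa share states, so one pruning call per
# taxon-subset shape covers every state labelling of that shape.
uninformative_classes <- function(n, k, cap = 1e7) {
  perm <- function(m, j) if (j > m) 0 else prod(seq.int(m, by = -1, length.out = j))
  pats <- list(); mult <- numeric(0); shape <- character(0)
  for (j in 0:min(n - 2, k - 1)) {
    subsets <- utils::combn(n, j)
    if (length(pats) + ncol(subsets) > cap)
      stop("correction infeasible: symmetry classes exceed cap ", cap)
    m_j <- k * perm(k - 1, j)
    for (s in seq_len(ncol(subsets))) {
      p <- integer(n)
      if (j > 0) p[subsets[, s]] <- seq_len(j)
      pats[[length(pats) + 1L]] <- p
      mult <- c(mult, m_j)
      shape <- c(shape, paste0("singletons{", paste(subsets[, s], collapse = ","), "}"))
    }
  }
  if (k >= n) {
    pats[[length(pats) + 1L]] <- 0:(n - 1)
    mult <- c(mult, perm(k, n))
    shape <- c(shape, "all_distinct")
  }
  list(patterns = do.call(cbind, pats), multiplicity = mult, shape = shape)
}

#' Probability mass of unobservable site patterns
#'
#' Computes `L_unobs`, the total Mk probability of the pattern class a
#' filtered matrix can never contain, on the current tree and branch
#' lengths.  `mode = "invariant"` (the Mkv correction) uses the state
#' symmetry of Mk: all `k` constant patterns are equally likely, so
#' `L_unobs = k * L(constant)`.  `mode = "parsinf"` sums over the distinct
#' parsimony-uninformative patterns by symmetry class — one pruning
#' evaluation per set of singleton taxa, multiplied by the number of state
#' labellings of that shape (for `k = 2` this is `1 + n` evaluations).
#'
#' @param tree a [dated_tree] with `char_lengths`.
#' @param k number of states.
#' @param mode `"invariant"` or `"parsinf"`.
#' @param cap maximum number of symmetry classes to evaluate.
#' @return object of class `correction_term`: list with `L_unobs`, `classes`
#'   (data.frame: shape, multiplicity, class likelihood), `mode`, `k`.
#' @export
unobservable_mass <- function(tree, k, mode = c("invariant", "parsinf"),
                              cap = 1e7) {
  mode <- match.arg(mode)
  n <- length(tree$phy$tip.label)
  if (mode == "parsinf" && n < 4)
    stop("parsinf correction undefined for fewer than 4 taxa ",
         "(no parsimony-informative pattern exists)")
  if (mode == "invariant") {
    cls <- list(patterns = matrix(0L, nrow = n), multiplicity = k,
                shape = "constant")
  } else {
    cls <- uninformative_classes(n, k, cap)
  }
  lik <- pattern_likelihoods(tree, cls$patterns, k)
  L_unobs <- sum(cls$multiplicity * lik)
  if (L_unobs >= 1 - 1e-12)
    stop(sprintf(
      "degenerate correction: L_unobs = %.15f >= 1 (tree too short or too few taxa)",
      L_unobs))
  structure(list(L_unobs = L_unobs,
                 classes = data.frame(shape = cls$shape,
                                      multiplicity = cls$multiplicity,
                                      class_lik = lik),
                 mode = mode, k = k),
            class = "correction_term")
}

#' @export
print.correction_term <- function(x, ...) {
  cat(sprintf("<correction_term> mode=%s k=%d: L_unobs = %.6g over %d symmetry classes\n",
              x$mode, x$k, x$L_unobs, nrow(x$classes)))
  invisible(x)
}

# map matrix rows into tree tip order; error on mismatch
align_to_tips <- function(x, tree) {
  tips <- tree$phy$tip.label
  if (!setequal(x$taxa, tips))
    stop("matrix taxa do not match tree tips")
  x$states[match(tips, x$taxa), , drop = FALSE]
}

compress_patterns <- function(states) {
  key <- apply(states, 2, function(col) paste(ifelse(is.na(col), "?", col),
                                              collapse = ","))
  ux <- !duplicated(key)
  list(patterns = states[, ux, drop = FALSE],
       weights = as.numeric(table(factor(key, levels = key[ux]))))
}

#' Ascertainment-corrected log-likelihood of a character matrix
#'
#' Plain Mk sums per-character pruning log-likelihoods.  Mkv and Mk-parsinf
#' divide every character likelihood by `1 - L_unobs` where `L_unobs` is
#' the probability mass of the unobservable class on the current branch
#' lengths ([unobservable_mass()]), computed once per state count.
#' Characters with different state counts are handled as independent blocks
#' and their contributions summed.
#'
#' @param x a [char_matrix].
#' @param tree a [dated_tree] with `char_lengths` set (or supply `rate` to
#'   use `durations * rate`).
#' @param config a [site_model]; its `k` is ignored in favour of the
#'   matrix's per-character state counts.
#' @param rate optional clock rate (substitutions/character/Ma) used to set
#'   `char_lengths = durations(tree) * rate`.
#' @return the log-likelihood (0 for an empty matrix).
#' @export
corrected_loglik <- function(x, tree, config, rate = NULL) {
  stopifnot(inherits(x, "char_matrix"), inherits(config, "site_model"))
  if (!is.null(rate))
    tree$char_lengths <- durations(tree) * rate
  if (ncol(x$states) == 0L) return(0)
  states <- align_to_tips(x, tree)
  if (config$model == "mkv") {
    inv <- vapply(seq_len(ncol(states)), function(j) {
      obs <- states[, j][!is.na(states[, j])]
      length(unique(obs)) <= 1L
    }, logical(1))
    if (any(inv))
      warning("Mkv applied to a matrix containing invariant characters ",
              "(the model assumes they are unobservable)")
  }
  total <- 0
  for (k in unique(x$n_states)) {
    block <- states[, x$n_states == k, drop = FALSE]
    cp <- compress_patterns(block)
    lik <- pattern_likelihoods(tree, cp$patterns, k)
    if (any(lik <= 0)) return(-Inf)
    log_corr <- switch(config$model,
      mk = 0,
      mkv = log1p(-unobservable_mass(tree, k, "invariant")$L_unobs),
      mkparsinf = log1p(-unobservable_mass(tree, k, "parsinf")$L_unobs))
    total <- total + sum(cp$weights * (log(lik) - log_corr))
  }
  total
}

#' Simulate discrete characters under Mk on a dated tree
#'
#' Root states are uniform on `k`; states evolve down each branch with the
#' Mk transition probabilities for that branch's expected-substitution
#' length (the tree's `char_lengths`, or `durations * rate`).  No missing
#' data are generated.
#'
#' @param tree a [dated_tree].
#' @param k number of states.
#' @param n_chars number of characters.
#' @param seed RNG seed (required: simulations are reproducible by contract).
#' @param rate optional clock rate; sets `char_lengths = durations * rate`.
#' @return a [char_matrix] with taxa in tree tip order.
#' @export
simulate_characters <- function(tree, k, n_chars, seed, rate = NULL) {
  stopifnot(k >= 2, n_chars >= 0)
  if (!is.null(rate)) tree$char_lengths <- durations(tree) * rate
  v <- char_branch_lengths(tree)
  set.seed(seed)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  states <- matrix(NA_integer_, nn, n_chars)
  states[ntip + 1L, ] <- sample.int(k, n_chars, replace = TRUE) - 1L
  # preorder: reverse postorder visits parents before children
  for (e in rev(ape::postorder(phy))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    p_same <- 1 / k + (k - 1) / k * exp(-v[e] * k / (k - 1))
    stay <- stats::runif(n_chars) < p_same
    shift <- sample.int(k - 1, n_chars, replace = TRUE)  # offset among others
    states[ch, ] <- ifelse(stay, states[par, ],
                           (states[par, ] + shift) %% k)
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  char_matrix(out, n_states = k)
}
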