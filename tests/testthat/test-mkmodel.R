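test_that("Mk transition probabilities follow the closed form", {
  expect_equal(mk_transition_matrix(3, 0), diag(3))
  expect_equal(mk_transition_matrix(4, 500), matrix(0.25, 4, 4),
               tolerance = 1e-12)
  m <- mk_transition_matrix(2, 0.2)
  expect_equal(m[1, 2], (1 - exp(-0.4)) / 2, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    k <- sample(2:6, 1); v1 <- runif(1, 0, 2); v2 <- runif(1, 0, 2)
    P1 <- mk_transition_matrix(k, v1)
    expect_equal(rowSums(P1), rep(1, k), tolerance = 1e-12)
    # Chapman-Kolmogorov
    expect_equal(P1 %*% mk_transition_matrix(k, v2),
                 mk_transition_matrix(k, v1 + v2), tolerance = 1e-12)
  }
  expect_error(mk_transition_matrix(2, -0.1), ">= 0")
})

cherry <- function(l1 = 0.2, l2 = 0.2) {
  tr <- dated_tree(ape::read.tree(text = "(A:1,B:1);"),
                   tip_ages = c(A = 0, B = 0))
  tr$char_lengths <- c(l1, l2)
  tr
}

test_that("pruning matches hand calculation on a two-tip cherry", {
  tr <- cherry()
  # reversibility collapses the cherry to a single path of length 0.4
  expect_equal(pruning_likelihood(tr, c(A = 0, B = 1), 2),
               0.5 * (1 - exp(-0.8)) / 2, tolerance = 1e-12)
  # zero character change possible: identity transitions
  tr0 <- cherry(0, 0)
  expect_equal(pruning_likelihood(tr0, c(A = 0, B = 0), 2), 0.5)
  expect_equal(pruning_likelihood(tr0, c(A = 0, B = 1), 2), 0)
  # all-missing column: likelihood 1
  expect_equal(pruning_likelihood(tr, c(A = NA, B = NA), 2), 1)
  expect_error(pruning_likelihood(tr, c(A = 0, X = 1), 2), "do not match")
})

test_that("pruning equals brute-force internal-state summation", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:5, 1); k <- sample(2:3, 1)
    tr <- random_dated_tree(n, seed = 1000 + i)
    tr$char_lengths <- runif(nrow(tr$phy$edge), 0, 1.5)
    column <- sample(c(0:(k - 1), NA), n, replace = TRUE)
    names(column) <- tr$phy$tip.label
    expect_equal(pruning_likelihood(tr, column, k),
                 brute_force_lik(tr, column, k), tolerance = 1e-12)
  }
})

test_that("unobservable mass matches closed forms and flags degeneracy", {
  tr <- cherry()
  um <- unobservable_mass(tr, 2, "invariant")
  expect_equal(um$L_unobs, 1 - (1 - exp(-0.8)) / 2, tolerance = 1e-12)
  expect_equal(sum(um$classes$multiplicity * um$classes$class_lik),
               um$L_unobs, tolerance = 1e-12)
  # (almost) zero-length tree: every character would be invariant
  expect_error(unobservable_mass(cherry(1e-16, 1e-16), 2, "invariant"),
               "degenerate")
  # three taxa: every pattern is parsimony-uninformative
  tr3 <- random_dated_tree(3, 5)
  tr3$char_lengths <- durations(tr3) * 0.3
  expect_error(unobservable_mass(tr3, 2, "parsinf"), "fewer than 4 taxa")
})

test_that("symmetry-class mass equals naive per-pattern summation", {
  for (seed in 1:10) {
    n <- sample(4:6, 1); k <- sample(2:3, 1)
    tr <- random_dated_tree(n, seed = 300 + seed)
    tr$char_lengths <- runif(nrow(tr$phy$edge), 0.05, 1)
    pats <- all_patterns(n, k)
    liks <- vapply(seq_len(nrow(pats)), function(i)
      pruning_likelihood(tr, setNames(pats[i, ], tr$phy$tip.label), k),
      numeric(1))
    uninf <- !apply(pats, 1, is_parsimony_informative, k = k)
    inv <- apply(pats, 1, function(p) length(unique(p)) == 1L)
    expect_equal(unobservable_mass(tr, k, "parsinf")$L_unobs,
                 sum(liks[uninf]), tolerance = 1e-12)
    expect_equal(unobservable_mass(tr, k, "invariant")$L_unobs,
                 sum(liks[inv]), tolerance = 1e-12)
  }
})

test_that("corrected likelihoods renormalise over the observable classes", {
  # Mkv on a cherry with the single variable column (0,1): exactly 1/2
  tr <- cherry()
  m <- char_matrix(rbind(A = 0L, B = 1L), n_states = 2L)
  expect_equal(corrected_loglik(m, tr, site_model("mkv")), log(0.5),
               tolerance = 1e-12)
  # Mk equals the sum of per-column pruning log-likelihoods
  tm <- toy_matrix()
  tr4 <- random_dated_tree(4, 77)
  tr4$phy$tip.label <- tm$taxa
  tr4$char_lengths <- durations(tr4) * 0.2
  by_hand <- sum(vapply(seq_len(6), function(j)
    log(pruning_likelihood(tr4, setNames(tm$states[, j], tm$taxa), 2)),
    numeric(1)))
  expect_equal(corrected_loglik(tm, tr4, site_model("mk")), by_hand,
               tolerance = 1e-10)
  # Mkv warns when the matrix still contains invariant characters
  expect_warning(corrected_loglik(tm, tr4, site_model("mkv")),
                 "invariant characters")
})

test_that("corrected per-pattern likelihoods sum to one over each class", {
  for (seed in 1:4) {
    n <- sample(4:6, 1); k <- sample(2:3, 1)
    tr <- random_dated_tree(n, seed = 600 + seed)
    tr$char_lengths <- runif(nrow(tr$phy$edge), 0.05, 0.8)
    pats <- all_patterns(n, k)
    liks <- vapply(seq_len(nrow(pats)), function(i)
      pruning_likelihood(tr, setNames(pats[i, ], tr$phy$tip.label), k),
      numeric(1))
    inv <- apply(pats, 1, function(p) length(unique(p)) == 1L)
    info <- apply(pats, 1, is_parsimony_informative, k = k)
    Lv <- unobservable_mass(tr, k, "invariant")$L_unobs
    Lp <- unobservable_mass(tr, k, "parsinf")$L_unobs
    expect_equal(sum(liks[!inv]) / (1 - Lv), 1, tolerance = 1e-10)
    expect_equal(sum(liks[info]) / (1 - Lp), 1, tolerance = 1e-10)
  }
})

test_that("character simulation is seeded, Mk-distributed and complete", {
  tr <- random_dated_tree(4, 9)
  tr$char_lengths <- rep(0, nrow(tr$phy$edge))
  m0 <- simulate_characters(tr, 2, 50, seed = 4)
  expect_true(all(apply(m0$states, 2, function(col) length(unique(col)) == 1)))
  tr$char_lengths <- runif(nrow(tr$phy$edge), 0.1, 0.8)
  m1 <- simulate_characters(tr, 2, 200, seed = 5)
  m2 <- simulate_characters(tr, 2, 200, seed = 5)
  expect_identical(m1$states, m2$states)
  expect_false(anyNA(m1$states))
  # simulated pattern frequencies match exact pattern probabilities
  big <- simulate_characters(tr, 2, 100000, seed = 6)
  pats <- all_patterns(4, 2)
  probs <- vapply(seq_len(nrow(pats)), function(i)
    pruning_likelihood(tr, setNames(pats[i, ], tr$phy$tip.label), 2),
    numeric(1))
  key <- apply(pats, 1, paste, collapse = "")
  obs <- table(factor(apply(big$states[tr$phy$tip.label, ], 2, paste,
                            collapse = ""), levels = key))
  expect_gt(stats::chisq.test(as.vector(obs), p = probs / sum(probs))$p.value,
            0.001)
})
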