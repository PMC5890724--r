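test_that("Fitch counting matches hand and brute-force results", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_steps(phy, c(A = 0, B = 0, C = 1, D = 1))$steps, 1L)
  expect_equal(fitch_steps(phy, c(A = 0, B = 1, C = 0, D = 1))$steps, 2L)
  expect_equal(fitch_steps(phy, c(A = 1, B = 1, C = 1, D = 1))$steps, 0L)
  # a most-parsimonious reconstruction realises the step count
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:6, 1); k <- sample(2:3, 1)
    phy <- ape::rtree(n)
    col <- sample(c(0:(k - 1), NA), n, replace = TRUE,
                  prob = c(rep(2, k), 1))
    if (all(is.na(col))) col[1] <- 0L
    names(col) <- phy$tip.label
    fs <- fitch_steps(phy, col, k)
    expect_equal(fs$steps, brute_force_steps(phy, col, k))
    expect_equal(sum(fs$changes), fs$steps)
  }
})

test_that("Fitch agrees with phangorn on missing-free columns", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    phy <- ape::rtree(n)
    col <- sample(0:1, n, replace = TRUE)
    names(col) <- phy$tip.label
    pd <- phangorn::phyDat(matrix(as.character(col), ncol = 1,
                                  dimnames = list(names(col), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(fitch_steps(phy, col, 2)$steps,
                 as.integer(phangorn::fitch(phy, pd)))
  }
})

test_that("root-to-tip regression separates clock from non-clock signal", {
  ds <- make_benchmark(bdss_params(n_tips = 20), n_chars = 500, seed = 99)
  rc <- root_to_tip_regression(ds$tree, ds$clock$full)
  expect_gt(rc$slope, 0)
  expect_lt(rc$p_value, 0.05)
  expect_true(rc$clocklike)
  # zero-variation matrix: flat regression
  inv <- char_matrix(matrix(0L, 20, 10,
                            dimnames = list(ds$tree$phy$tip.label, NULL)))
  r0 <- root_to_tip_regression(ds$tree, inv)
  expect_equal(r0$slope, 0)
  expect_equal(r0$r_squared, 0)
  expect_false(r0$clocklike)
  # all tips the same age: no regression possible
  iso <- random_dated_tree(6, 2)
  iso$ages[1:6] <- 0
  iso$phy$edge.length <- autapodate:::ages_to_durations(iso$phy, iso$ages)
  m6 <- simulate_characters({iso$char_lengths <- durations(iso) * 0.3; iso},
                            2, 30, seed = 1)
  expect_error(root_to_tip_regression(iso, m6), "same age")
})

test_that("signed-rank p-values match conventions and oracles", {
  expect_equal(wilcoxon_signed_rank(c(0, 0, 0))$p_value, 1)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p_value, 0.25)  # 2/8
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3),
                                    alternative = "greater")$p_value, 0.125)
  # tie-free exact cases against stats::wilcox.test
  set.seed(8)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    for (alt in c("two_sided", "less", "greater")) {
      ref <- stats::wilcox.test(d, alternative = sub("_sided", ".sided", alt),
                                exact = TRUE)$p.value
      expect_equal(wilcoxon_signed_rank(d, alternative = alt)$p_value, ref,
                   tolerance = 1e-12, label = paste("n =", n, alt))
    }
  }
  # with ties: independent enumeration over sign assignments
  d <- c(1, 1, -2, 3, 3)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  dist <- signs %*% r
  W <- sum(r[d > 0])
  expect_equal(wilcoxon_signed_rank(d, alternative = "greater")$p_value,
               mean(dist >= W))
  # normal approximation close to exact enumeration at n = 14
  set.seed(9)
  for (i in 1:10) {
    d <- rnorm(14)
    exact <- wilcoxon_signed_rank(d)$p_value
    big <- wilcoxon_signed_rank(c(d, 1e-9 * rnorm(7)))  # n = 21: normal path
    expect_equal(big$method, "normal")
    # compare the two computational paths on the same 14 pairs
    mu <- 14 * 15 / 4; sig2 <- 14 * 15 * 29 / 24
    W <- wilcoxon_signed_rank(d)$statistic
    p_norm <- 2 * min(pnorm((W - mu - 0.5) / sqrt(sig2), lower.tail = FALSE),
                      pnorm((W - mu + 0.5) / sqrt(sig2)))
    expect_lt(abs(exact - min(1, p_norm)), 0.02)
  }
})

test_that("a reduced experiment produces a complete, deterministic report", {
  rep1 <- run_experiment(bdss_params(n_tips = 10), n_chars = 60, seeds = 1,
                         iterations = 3000, thin = 30,
                         nonclock_iterations = 3000)
  expect_s3_class(rep1, "experiment_report")
  expect_equal(nrow(rep1$run_table), 5L)   # 2x2 contrast cells + coverage run
  expect_equal(nrow(rep1$summary), 1L)
  expect_true(all(c("p_terminal_bias_onesided", "p_nonclock_ages_twosided",
                    "coverage_clock_full") %in% names(rep1$summary)))
  ps <- rep1$per_seed[["1"]]
  expect_equal(nrow(ps$errors$clock_variable), 18L)  # 2n - 2 branches
  # regeneration with the same config is bit-identical
  rep2 <- run_experiment(bdss_params(n_tips = 10), n_chars = 60, seeds = 1,
                         iterations = 3000, thin = 30,
                         nonclock_iterations = 3000)
  expect_identical(rep1$summary, rep2$summary)
  expect_identical(rep1$run_table, rep2$run_table)
  # on-disk report
  dir <- withr::local_tempdir()
  run_experiment(bdss_params(n_tips = 10), n_chars = 60, seeds = 1,
                 iterations = 3000, thin = 30, nonclock_iterations = 3000,
                 out_dir = dir)
  expect_true(all(c("report.json", "summaries.tsv", "run_table.tsv") %in%
                    list.files(dir)))
  expect_length(list.files(dir, pattern = "_trace\\.tsv$"), 5L)
})

test_that("relaxed clocks report more rate variation on reshuffled data", {
  wins <- 0L
  for (s in 1:3) {
    ds <- make_benchmark(bdss_params(n_tips = 15), n_chars = 300,
                         seed = 7000 + s)
    pr <- list(root_cap_offset = 10, sigma_rate = 1 / 3)
    fc <- tipdate(ds$clock$full, ds$tree, clock = "ucln", iterations = 2e4,
                  thin = 40, seed = 1, priors = pr)
    fn <- tipdate(ds$nonclock$full, ds$tree, clock = "ucln", iterations = 2e4,
                  thin = 40, seed = 1, priors = pr)
    if (coef(fn)["clock_sd"] > coef(fc)["clock_sd"]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
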