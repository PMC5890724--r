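#' Classify a character column by parsimony informativeness
#'
#' A column is \emph{parsimony informative} when at least two states each
#' occur in at least two scored taxa; \emph{invariant} when exactly one state
#' occurs; \emph{autapomorphic} when exactly two states occur and one of them
#' in exactly one taxon; any other variable column (two or more singleton
#' states, no second doubly-observed state) is \emph{uninformative variable}.
#' Missing cells are ignored when tallying state multiplicities.
#'
#' @param column integer vector of states, `NA` for missing.
#' @param k number of states the character can take (used for validation).
#' @return an object of class `pattern_class`: a list with elements `label`
#'   (one of `"invariant"`, `"autapomorphic"`, `"uninformative_variable"`,
#'   `"parsimony_informative"`) and `counts` (named state multiplicities
#'   among scored taxa).
#' @export
classify_column <- function(column, k = max(column, na.rm = TRUE) + 1L) {
  scored <- column[!is.na(column)]
  if (length(scored) == 0L)
    stop("cannot classify an all-missing column")
  if (any(scored < 0 | scored >= k))
    stop("observed state outside 0..k-1")
  tab <- table(scored)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  n_states <- length(counts)
  label <-
    if (n_states == 1L) "invariant"
    else if (sum(counts >= 2L) >= 2L) "parsimony_informative"
    else if (n_states == 2L && min(counts) == 1L) "autapomorphic"
    else "uninformative_variable"
  structure(list(label = label, counts = counts), class = "pattern_class")
}

#' @export
print.pattern_class <- function(x, ...) {
  cat("<pattern_class>", x$label, "| multiplicities:",
      paste(names(x$counts), x$counts, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Partition a character matrix by pattern class
#'
#' Classifies every character and derives the ascertainment-filtered
#' matrices: `variable_only` (invariant characters dropped — the data an Mkv
#' analysis assumes) and `parsinf_only` (only parsimony-informative
#' characters — the data a parsimony-era matrix retains).  Taxon order and
#' character identifiers are preserved through filtering.
#'
#' @param x a [char_matrix].
#' @return an object of class `matrix_partition`: list with `classes`
#'   (character vector per character), `counts` (per-class tallies),
#'   `full`, `variable_only`, `parsinf_only` (each a [char_matrix]).
#' @export
partition_matrix <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  nc <- ncol(x$states)
  cls <- character(nc)
  for (j in seq_len(nc))
    cls[j] <- classify_column(x$states[, j], x$n_states[j])$label
  lv <- c("invariant", "autapomorphic", "uninformative_variable",
          "parsimony_informative")
  counts <- table(factor(cls, levels = lv))
  keep_var <- cls != "invariant"
  keep_pi <- cls == "parsimony_informative"
  if (!any(keep_pi) && nc > 0L)
    warning("no parsimony-informative characters; parsinf_only matrix is empty")
  structure(list(
    classes = cls,
    counts = counts,
    full = x,
    variable_only = subset_chars(x, keep_var),
    parsinf_only = subset_chars(x, keep_pi)
  ), class = "matrix_partition")
}

#' @export
print.matrix_partition <- function(x, ...) {
  cat("<matrix_partition>", ncol(x$full$states), "characters:\n")
  print(x$counts)
  invisible(x)
}

falling_factorial_terms <- function(n, k, j_max) {
  # term_j = k * C(n, j) * (k-1)! / (k-1-j)!  computed incrementally and
  # exactly: t_j = t_{j-1} * (n-j+1) * (k-j) / j
  t <- exactint(k)
  total <- t
  j <- 0L
  while (j < j_max) {
    j <- j + 1L
    t <- exact_div_small(exact_mul_small(exact_mul_small(t, n - j + 1), k - j), j)
    total <- exact_add(total, t)
  }
  total
}

#' Number of likelihood terms in the parsimony-informative correction
#'
#' Counts the site-pattern terms the Mk-parsinf ascertainment-bias
#' correction enumerates for `n` taxa and `k` states: choose a background
#' state (`k` ways), choose `j` deviant taxa, and give each a distinct
#' non-background state, summed over `j = 0..min(n, k-1)`.  Exact integer
#' arithmetic throughout; this count grows combinatorially in `k`, which is
#' why the correction is impractical for many-state characters.
#'
#' @param n number of taxa (>= 1).
#' @param k number of states (>= 1).
#' @return an [exactint]; use `as.numeric()` or `as.character()`.
#' @seealso [count_distinct_uninformative()] for the number of distinct
#'   uninformative patterns, which is smaller when `k >= n - 1` because
#'   all-distinct patterns are reached from several background states.
#' @export
count_parsinf_terms <- function(n, k) {
  stopifnot(n >= 1, k >= 1, n == floor(n), k == floor(k))
  falling_factorial_terms(n, k, min(n, k - 1))
}

#' Number of distinct parsimony-uninformative site patterns
#'
#' Counts distinct patterns over `n` taxa and `k` states in which at most
#' one state occurs in two or more taxa: a background state seen `n - j >= 2`
#' times plus `j` distinct singleton states (`j <= n - 2`), plus — when
#' `k >= n` — the patterns where every taxon shows a different state, each
#' counted once.  Agrees with brute-force enumeration; equals
#' [count_parsinf_terms()] whenever `k <= n - 2`.
#'
#' @inheritParams count_parsinf_terms
#' @return an [exactint].
#' @export
count_distinct_uninformative <- function(n, k) {
  stopifnot(n >= 1, k >= 1, n == floor(n), k == floor(k))
  if (n == 1L) return(exactint(k))
  total <- falling_factorial_terms(n, k, min(n - 2, k - 1))
  if (k >= n) {
    # all-distinct patterns: k * (k-1) * ... * (k-n+1)
    ad <- exactint(1)
    for (i in 0:(n - 1)) ad <- exact_mul_small(ad, k - i)
    total <- exact_add(total, ad)
  }
  total
}

#' Enumerate the distinct parsimony-uninformative site patterns
#'
#' Emits, in lexicographic order, every distinct pattern over `n` taxa and
#' `k` states that a parsimony-informative-only matrix can never contain.
#' The complement over all `k^n` patterns is exactly the
#' parsimony-informative set.  Refuses to enumerate when `k^n` exceeds
#' `cap` — the point at which the correction becomes computationally
#' impractical — with an error reporting the required count.
#'
#' @inheritParams count_parsinf_terms
#' @param cap maximum total pattern count `k^n` to enumerate (default 1e7).
#' @return integer matrix, one row per pattern, `n` columns of states.
#' @export
enumerate_uninformative_patterns <- function(n, k, cap = 1e7) {
  stopifnot(n >= 1, k >= 1)
  if (k^n > cap)
    stop(sprintf(
      "enumeration infeasible: k^n = %s patterns exceeds cap %s (distinct uninformative patterns: %s)",
      format(k^n, big.mark = ","), format(cap, big.mark = ","),
      as.character(count_distinct_uninformative(n, k))))
  total <- as.integer(k^n)
  idx <- 0:(total - 1L)
  # lexicographic: first taxon is the most significant digit
  pat <- matrix(0L, nrow = total, ncol = n)
  rest <- idx
  for (j in n:1) {
    pat[, j] <- rest %% k
    rest <- rest %/% k
  }
  keep <- vapply(seq_len(total), function(i) {
    counts <- tabulate(pat[i, ] + 1L, nbins = k)
    sum(counts >= 2L) < 2L
  }, logical(1))
  pat[keep, , drop = FALSE]
}
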