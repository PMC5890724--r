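#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted samples containing
#' `ceiling(level * N)` of them; ties broken by the lowest start.
#'
#' @param samples numeric vector (>= 2 values, or 1 for a degenerate chain).
#' @param level coverage level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (length(samples) == 0L) stop("empty sample vector")
  s <- sort(samples)
  n <- length(s)
  m <- min(n, ceiling(level * n))
  if (m == n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first (lowest start) on ties
  c(s[i], s[i + m - 1L])
}

#' Effective sample size of an MCMC chain
#'
#' `N / (1 + 2 * sum(rho_t))` with Geyer initial-positive-sequence
#' truncation of the autocorrelation sum.  A constant chain is flagged and
#' reported as ESS = N.
#'
#' @param x numeric chain.
#' @return ESS, with attribute `constant = TRUE` for zero-variance chains.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0) {
    return(structure(as.numeric(n), constant = TRUE))
  }
  lag_max <- min(n - 1L, max(50L, floor(10 * log10(n))))
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  # Geyer: sum consecutive pairs Gamma_m = rho_{2m} + rho_{2m+1} while > 0
  tau <- 0
  m <- 1L
  while (m <= length(rho)) {
    g <- rho[m] + if (m + 1L <= length(rho)) rho[m + 1L] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
    m <- m + 2L
  }
  tau <- max(tau - 1, 1e-8)  # tau = 1 + 2*sum(rho_{t>=1}); rho_0 counted twice
  structure(n / tau, constant = FALSE)
}

#' Summarise an MCMC trace
#'
#' Post-burn-in mean, 95% HPD and ESS for every sampled parameter.
#'
#' @param trace data.frame of samples (a `tipdate_fit$trace`), with a
#'   `state` index column.
#' @param burnin fraction of samples discarded (default 0.25; must be < 1).
#' @param level HPD level.
#' @return data.frame: parameter, mean, hpd_low, hpd_high, ess, constant.
#' @export
summarize_trace <- function(trace, burnin = 0.25, level = 0.95) {
  stopifnot(burnin >= 0, burnin < 1)
  drop <- seq_len(floor(burnin * nrow(trace)))
  keep <- if (length(drop)) trace[-drop, , drop = FALSE] else trace
  if (nrow(keep) == 0L) stop("no samples left after burn-in")
  pars <- setdiff(names(keep), "state")
  rows <- lapply(pars, function(p) {
    v <- keep[[p]]
    h <- hpd_interval(v, level)
    e <- ess(v)
    data.frame(parameter = p, mean = mean(v), hpd_low = h[1], hpd_high = h[2],
               ess = as.numeric(e), constant = isTRUE(attr(e, "constant")))
  })
  do.call(rbind, rows)
}

#' Sample internal node ages from the tip-dating prior
#'
#' Direct rejection sampling from the uniform-given-constraints node-age
#' prior (each internal age uniform subject to parent > child and root age
#' below the cap).  Used for prior-recovery validation of the MCMC.
#'
#' @param tree a [dated_tree] (fixes topology and tip ages).
#' @param n number of draws.
#' @param seed RNG seed.
#' @param root_cap_offset root age cap = oldest tip age + this (Ma).
#' @return matrix `n x Nnode` of internal ages (columns in ape node order).
#' @export
sample_node_age_prior <- function(tree, n, seed,
                                  root_cap_offset = 50) {
  set.seed(seed)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  cap <- max(tip_ages(tree)) + root_cap_offset
  # minimum feasible age per internal node: max descendant tip age
  lb <- numeric(ntip + phy$Nnode)
  lb[seq_len(ntip)] <- tree$ages[seq_len(ntip)]
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    lb[p] <- max(lb[p], lb[ch])
  }
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  out <- matrix(NA_real_, n, phy$Nnode)
  ids <- (ntip + 1L):(ntip + phy$Nnode)
  got <- 0L
  while (got < n) {
    a <- tree$ages
    a[ids] <- stats::runif(phy$Nnode, lb[ids], cap)
    ok <- TRUE
    for (i in ids) if (parent[i] != 0L && a[parent[i]] <= a[i]) { ok <- FALSE; break }
    if (ok) { got <- got + 1L; out[got, ] <- a[ids] }
  }
  colnames(out) <- paste0("age_", ids)
  out
}

default_priors <- function() {
  list(clock_mean_meanlog = log(0.1), clock_mean_sdlog = 2,
       sigma_rate = 1, root_cap_offset = 50)
}

#' Bayesian tip-dating on a fixed topology
#'
#' Fits node ages and clock parameters by Metropolis-Hastings MCMC, holding
#' the topology and the fossil tip dates fixed.  The likelihood is the
#' (optionally ascertainment-corrected) Mk likelihood of the character
#' matrix with branch lengths `duration * clock_mean * multiplier`
#' (multipliers are 1 under the strict clock; under the uncorrelated
#' lognormal relaxed clock they are iid lognormal with log-mean
#' `-sigma^2/2`, so their expectation is 1 and `clock_mean` stays
#' identifiable).  Priors: internal node ages uniform subject to
#' parent > child and a root-age cap (oldest tip + 50 Ma by default);
#' `clock_mean ~ lognormal(log 0.1, 2)`; `sigma ~ Exponential(1)`.
#' Moves: uniform-window slides of single node ages within their feasible
#' interval, and multiplicative scale moves for `clock_mean`, `sigma` and
#' individual branch multipliers.
#'
#' @param x a [char_matrix] (may have zero characters: the posterior is
#'   then the prior, used for validation).
#' @param tree a [dated_tree] giving topology, tip dates and the initial
#'   internal ages.
#' @param model a [site_model] (`"mk"`, `"mkv"`, `"mkparsinf"`).
#' @param clock `"strict"` or `"ucln"`.
#' @param iterations MCMC iterations.
#' @param thin sampling interval.
#' @param seed RNG seed; identical seeds give identical traces.
#' @param priors list overriding [default_priors()] entries.
#' @param init list with optional `clock_mean`, `sigma` starting values.
#' @param keep_rates store per-branch multipliers in the trace (ucln).
#' @return object of class `tipdate_fit`: list with `trace` (data.frame:
#'   state, posterior, likelihood, prior, root_age, clock_mean, clock_sd,
#'   age_* per internal node), `acceptance` (per move type), `config`,
#'   `tree`, `burnin` default.
#' @export
tipdate <- function(x, tree, model = site_model("mk"),
                    clock = c("strict", "ucln"),
                    iterations = 2e5, thin = 100, seed = 1,
                    priors = list(), init = list(), keep_rates = FALSE) {
  clock <- match.arg(clock)
  stopifnot(inherits(x, "char_matrix"), inherits(tree, "dated_tree"),
            inherits(model, "site_model"))
  pr <- utils::modifyList(default_priors(), priors)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  nedge <- nrow(phy$edge)
  edge <- phy$edge
  po <- ape::postorder(phy)
  parent <- integer(ntip + nnode); parent[edge[, 2]] <- edge[, 1]
  children <- vector("list", ntip + nnode)
  for (e in seq_len(nedge))
    children[[edge[e, 1]]] <- c(children[[edge[e, 1]]], edge[e, 2])
  cap <- max(tip_ages(tree)) + pr$root_cap_offset
  root <- ntip + 1L

  # data blocks by state count, pattern-compressed, tip-order aligned
  blocks <- list()
  if (ncol(x$states) > 0L) {
    states <- align_to_tips(x, tree)
    for (k in unique(x$n_states)) {
      cp <- compress_patterns(states[, x$n_states == k, drop = FALSE])
      corr <- switch(model$model,
        mk = NULL,
        mkv = list(patterns = matrix(0L, nrow = ntip), multiplicity = k),
        mkparsinf = {
          if (ntip < 4) stop("parsinf correction needs >= 4 taxa")
          cl <- uninformative_classes(ntip, k)
          list(patterns = cl$patterns, multiplicity = cl$multiplicity)
        })
      blocks[[length(blocks) + 1L]] <-
        list(k = as.integer(k), patterns = cp$patterns,
             weights = cp$weights, corr = corr)
    }
  }
  loglik_fun <- function(vsubst) {
    ll <- 0
    for (b in blocks) {
      lik <- mk_pattern_lik(edge, vsubst, po, ntip, nnode, b$patterns, b$k)
      if (any(lik <= 0)) return(-Inf)
      if (!is.null(b$corr)) {
        cl <- mk_pattern_lik(edge, vsubst, po, ntip, nnode, b$corr$patterns, b$k)
        L_unobs <- sum(b$corr$multiplicity * cl)
        if (L_unobs >= 1 - 1e-12) return(-Inf)
        ll <- ll - sum(b$weights) * log1p(-L_unobs)
      }
      ll <- ll + sum(b$weights * log(lik))
    }
    ll
  }
  logprior_fun <- function(clock_mean, sigma, mult) {
    lp <- stats::dlnorm(clock_mean, pr$clock_mean_meanlog,
                        pr$clock_mean_sdlog, log = TRUE)
    if (clock == "ucln")
      lp <- lp + stats::dexp(sigma, pr$sigma_rate, log = TRUE) +
        sum(stats::dlnorm(mult, -sigma^2 / 2, sigma, log = TRUE))
    lp
  }

  set.seed(seed)
  ages <- tree$ages
  clock_mean <- if (!is.null(init$clock_mean)) init$clock_mean else
    exp(pr$clock_mean_meanlog)
  sigma <- if (!is.null(init$sigma)) init$sigma else 0.1
  mult <- rep(1, nedge)
  dur <- ages[edge[, 1]] - ages[edge[, 2]]
  cur_ll <- loglik_fun(dur * clock_mean * mult)
  cur_lp <- logprior_fun(clock_mean, sigma, mult)
  if (!is.finite(cur_ll)) stop("infeasible starting state (likelihood is -Inf)")

  # under ucln, half the node-age updates preserve substitution lengths by
  # rescaling the multipliers on adjacent branches (likelihood-neutral), so
  # ages mix at prior speed instead of being pinned by the branch rates
  move_p <- if (clock == "strict")
    c(age = 0.6, age_pres = 0, scale = 0.15, scale_pres = 0, clock = 0.25,
      sigma = 0, mult = 0)
  else c(age = 0.2, age_pres = 0.2, scale = 0.08, scale_pres = 0.12,
         clock = 0.17, sigma = 0.08, mult = 0.15)
  edges_adj <- lapply(seq_len(ntip + nnode), function(nd)
    which(edge[, 1] == nd | edge[, 2] == nd))
  # scale-move windows, tuned toward ~30% acceptance during burn-in
  w <- c(scale = 0.1, scale_pres = 0.2, clock = 0.5, sigma = 0.5, mult = 0.5)
  adapt_until <- floor(0.25 * iterations)
  win_prop <- win_acc <- c(scale = 0, scale_pres = 0, clock = 0, sigma = 0,
                           mult = 0)
  n_prop <- c(age = 0, age_pres = 0, scale = 0, scale_pres = 0, clock = 0,
              sigma = 0, mult = 0)
  n_acc <- n_prop
  move_cum <- cumsum(move_p)
  move_names <- names(move_p)
  internal_ids <- (ntip + 1L):(ntip + nnode)

  n_samp <- floor(iterations / thin)
  extra <- if (clock == "ucln" && keep_rates) nedge else 0L
  tr <- matrix(NA_real_, n_samp, 6L + nnode + extra)
  samp_row <- 0L

  for (it in seq_len(iterations)) {
    u <- stats::runif(1)
    type <- move_names[which(u < move_cum)[1]]
    n_prop[type] <- n_prop[type] + 1
    if (type == "age") {
      nd <- internal_ids[if (nnode == 1L) 1L else sample.int(nnode, 1L)]
      ub <- if (nd == root) cap else ages[parent[nd]]
      lb <- max(ages[children[[nd]]])
      new_age <- stats::runif(1, lb, ub)
      old_age <- ages[nd]
      ages[nd] <- new_age
      new_dur <- ages[edge[, 1]] - ages[edge[, 2]]
      new_ll <- loglik_fun(new_dur * clock_mean * mult)
      if (log(stats::runif(1)) < new_ll - cur_ll) {
        cur_ll <- new_ll; dur <- new_dur; n_acc[type] <- n_acc[type] + 1
      } else ages[nd] <- old_age
    } else if (type == "age_pres") {
      nd <- internal_ids[if (nnode == 1L) 1L else sample.int(nnode, 1L)]
      ub <- if (nd == root) cap else ages[parent[nd]]
      lb <- max(ages[children[[nd]]])
      new_age <- stats::runif(1, lb, ub)
      adj <- edges_adj[[nd]]
      old_age <- ages[nd]
      ages[nd] <- new_age
      d_new <- ages[edge[adj, 1]] - ages[edge[adj, 2]]
      d_old <- dur[adj]
      m_new <- mult[adj] * d_old / d_new
      log_r <- sum(stats::dlnorm(m_new, -sigma^2 / 2, sigma, log = TRUE) -
                     stats::dlnorm(mult[adj], -sigma^2 / 2, sigma, log = TRUE)) +
        sum(log(d_old) - log(d_new))
      if (log(stats::runif(1)) < log_r) {
        dur[adj] <- d_new
        mult[adj] <- m_new
        cur_lp <- logprior_fun(clock_mean, sigma, mult)
        n_acc[type] <- n_acc[type] + 1
      } else ages[nd] <- old_age
    } else if (type == "scale_pres") {
      # global timescale move, likelihood-neutral: scale internal ages,
      # rescale every multiplier to keep substitution lengths fixed
      f <- exp(stats::runif(1, -w["scale_pres"], w["scale_pres"]))
      new_ages <- ages
      new_ages[internal_ids] <- ages[internal_ids] * f
      new_dur <- new_ages[edge[, 1]] - new_ages[edge[, 2]]
      acc <- FALSE
      if (all(new_dur > 0) && new_ages[root] <= cap) {
        m_new <- mult * dur / new_dur
        log_r <- sum(stats::dlnorm(m_new, -sigma^2 / 2, sigma, log = TRUE) -
                       stats::dlnorm(mult, -sigma^2 / 2, sigma, log = TRUE)) +
          sum(log(dur) - log(new_dur)) + nnode * log(f)
        if (log(stats::runif(1)) < log_r) {
          ages <- new_ages; dur <- new_dur; mult <- m_new
          cur_lp <- logprior_fun(clock_mean, sigma, mult)
          n_acc[type] <- n_acc[type] + 1
          acc <- TRUE
        }
      }
      if (it <= adapt_until) {
        win_prop[type] <- win_prop[type] + 1
        if (acc) win_acc[type] <- win_acc[type] + 1
        if (win_prop[type] == 50) {
          w[type] <- min(3, max(0.005, w[type] * exp(win_acc[type] / 50 - 0.3)))
          win_prop[type] <- win_acc[type] <- 0
        }
      }
    } else if (type == "scale") {
      # multiply all internal ages; mixes the tree-wide timescale dimension
      f <- exp(stats::runif(1, -w["scale"], w["scale"]))
      new_ages <- ages
      new_ages[internal_ids] <- ages[internal_ids] * f
      new_dur <- new_ages[edge[, 1]] - new_ages[edge[, 2]]
      if (all(new_dur > 0) && new_ages[root] <= cap) {
        new_ll <- loglik_fun(new_dur * clock_mean * mult)
        # Hastings: Jacobian of scaling nnode ages by f
        if (log(stats::runif(1)) < new_ll - cur_ll + nnode * log(f)) {
          ages <- new_ages; dur <- new_dur; cur_ll <- new_ll
          n_acc[type] <- n_acc[type] + 1
          acc <- TRUE
        } else acc <- FALSE
      } else acc <- FALSE
      if (it <= adapt_until) {
        win_prop[type] <- win_prop[type] + 1
        if (acc) win_acc[type] <- win_acc[type] + 1
        if (win_prop[type] == 50) {
          w[type] <- min(3, max(0.005, w[type] * exp(win_acc[type] / 50 - 0.3)))
          win_prop[type] <- win_acc[type] <- 0
        }
      }
    } else {
      acc <- FALSE
      f <- exp(stats::runif(1, -w[type], w[type]))
      if (type == "clock") {
        new_clock <- clock_mean * f
        new_ll <- loglik_fun(dur * new_clock * mult)
        new_lp <- logprior_fun(new_clock, sigma, mult)
        if (log(stats::runif(1)) < new_ll - cur_ll + new_lp - cur_lp + log(f)) {
          clock_mean <- new_clock; cur_ll <- new_ll; cur_lp <- new_lp
          acc <- TRUE
        }
      } else if (type == "sigma") {
        new_sigma <- sigma * f
        new_lp <- logprior_fun(clock_mean, new_sigma, mult)
        if (log(stats::runif(1)) < new_lp - cur_lp + log(f)) {
          sigma <- new_sigma; cur_lp <- new_lp; acc <- TRUE
        }
      } else {
        e <- if (nedge == 1L) 1L else sample.int(nedge, 1L)
        new_mult <- mult
        new_mult[e] <- mult[e] * f
        new_ll <- loglik_fun(dur * clock_mean * new_mult)
        new_lp <- logprior_fun(clock_mean, sigma, new_mult)
        if (log(stats::runif(1)) < new_ll - cur_ll + new_lp - cur_lp + log(f)) {
          mult <- new_mult; cur_ll <- new_ll; cur_lp <- new_lp; acc <- TRUE
        }
      }
      if (acc) n_acc[type] <- n_acc[type] + 1
      if (it <= adapt_until) {
        win_prop[type] <- win_prop[type] + 1
        if (acc) win_acc[type] <- win_acc[type] + 1
        if (win_prop[type] == 50) {
          rate <- win_acc[type] / 50
          w[type] <- min(3, max(0.01, w[type] * exp(rate - 0.3)))
          win_prop[type] <- win_acc[type] <- 0
        }
      }
    }
    if (it %% thin == 0L) {
      samp_row <- samp_row + 1L
      row <- c(it, cur_ll + cur_lp, cur_ll, cur_lp, ages[root], clock_mean,
               if (clock == "ucln") sigma else 0, ages[internal_ids][-1L])
      if (extra > 0L) row <- c(row, mult)
      tr[samp_row, ] <- row
    }
  }
  trace <- as.data.frame(tr[seq_len(samp_row), , drop = FALSE])
  names(trace) <- c("state", "posterior", "likelihood", "prior", "root_age",
                    "clock_mean", "clock_sd",
                    paste0("age_", internal_ids[-1L]),
                    if (extra > 0L) paste0("mult_", seq_len(nedge)))
  # root_age column doubles as age_<root id>; keep both views consistent
  structure(list(
    trace = trace,
    acceptance = ifelse(n_prop > 0, n_acc / n_prop, NA_real_),
    config = list(model = model, clock = clock, iterations = iterations,
                  thin = thin, seed = seed, priors = pr,
                  n_chars = ncol(x$states), n_taxa = ntip),
    tree = tree, burnin = 0.25), class = "tipdate_fit")
}

# internal-age posterior matrix (post burn-in), columns in ape node order
fit_age_samples <- function(fit, burnin = fit$burnin) {
  tr <- fit$trace
  drop <- seq_len(floor(burnin * nrow(tr)))
  keep <- if (length(drop)) tr[-drop, , drop = FALSE] else tr
  ntip <- length(fit$tree$phy$tip.label)
  ids <- (ntip + 1L):(ntip + fit$tree$phy$Nnode)
  m <- cbind(keep$root_age,
             as.matrix(keep[, paste0("age_", ids[-1L]), drop = FALSE]))
  colnames(m) <- paste0("age_", ids)
  m
}

#' @export
print.tipdate_fit <- function(x, ...) {
  cat(sprintf(
    "<tipdate_fit> %s / %s clock, %d characters, %d taxa, %d iterations (thin %d)\n",
    x$config$model$model, x$config$clock, x$config$n_chars, x$config$n_taxa,
    x$config$iterations, x$config$thin))
  cat(sprintf("  acceptance: %s\n",
              paste(names(x$acceptance),
                    sprintf("%.2f", x$acceptance), collapse = " ")))
  s <- summarize_trace(x$trace[, c("state", "root_age", "clock_mean")],
                       burnin = x$burnin)
  cat(sprintf("  root age %.3f [%.3f, %.3f] Ma, clock mean %.4g\n",
              s$mean[1], s$hpd_low[1], s$hpd_high[1], s$mean[2]))
  invisible(x)
}

#' @export
summary.tipdate_fit <- function(object, burnin = object$burnin, ...) {
  cols <- setdiff(names(object$trace), "state")
  out <- summarize_trace(object$trace[, c("state", cols)], burnin = burnin)
  class(out) <- c("summary.tipdate_fit", class(out))
  out
}

#' @export
print.summary.tipdate_fit <- function(x, ...) {
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tipdate_fit <- function(object, ...) {
  s <- summarize_trace(object$trace[, c("state", "root_age", "clock_mean",
                                        "clock_sd")],
                       burnin = object$burnin)
  stats::setNames(s$mean, s$parameter)
}

#' @export
plot.tipdate_fit <- function(x, pars = c("posterior", "root_age",
                                         "clock_mean"), ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars)
    graphics::plot(x$trace$state, x$trace[[p]], type = "l",
                   xlab = "state", ylab = p, ...)
  invisible(x)
}

#' Write / read an MCMC trace as tab-separated samples
#'
#' Header row then one row per retained sample (`state`, `posterior`,
#' `likelihood`, `prior`, `root_age`, `clock_mean`, `clock_sd`, node ages,
#' any stored branch rates).
#'
#' @param trace a trace data.frame (e.g. `fit$trace`).
#' @param path output TSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
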