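# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: exhaustive agglomeration for Ward, pair counting for the
# Rand index, full table enumeration for Fisher, direct product-limit and
# Efron partial-likelihood formulas for the survival models.

# exhaustive Ward agglomeration: at every step evaluate the increase in
# total within-cluster sum of squares for every cluster pair and merge the
# minimum; returns the partition at each level
oracle_ward_partitions <- function(x) {
  ess <- function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_len(a - 1)) {
      cost <- ess(c(clusters[[a]], clusters[[b]])) -
        ess(clusters[[a]]) - ess(clusters[[b]])
      if (cost < best_cost) { best_cost <- cost; best <- c(a, b) }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
    clusters[[best[1]]] <- NULL
    lab <- integer(nrow(x))
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[as.character(length(clusters))]] <- lab
  }
  partitions
}

# adjusted Rand index by pair counting (not the contingency-table formula
# the implementation uses)
oracle_ari_paircount <- function(a, b) {
  n <- length(a)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd <- sd + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  m <- n * (n - 1) / 2
  expected <- (ss + sd) * (ss + ds) / m
  maximum <- ((ss + sd) + (ss + ds)) / 2
  if (maximum == expected) return(1)
  (ss - expected) / (maximum - expected)
}

# exact Fisher p for an r x c table: enumerate all tables with the
# observed margins; two-sided p sums probabilities <= observed
oracle_fisher_exact <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  log_prob <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  }
  tables <- list()
  fill <- function(partial, row) {
    if (row == length(rs)) {
      last <- cs - colSums(matrix(unlist(partial), ncol = length(cs),
                                  byrow = TRUE))
      if (all(last >= 0)) tables[[length(tables) + 1]] <<-
          rbind(do.call(rbind, partial), last)
      return(invisible())
    }
    cells <- enumerate_row(rs[row], cs - if (length(partial))
      colSums(matrix(unlist(partial), ncol = length(cs), byrow = TRUE))
      else rep(0, length(cs)))
    for (cell in cells) fill(c(partial, list(cell)), row + 1)
  }
  enumerate_row <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (v in 0:min(total, caps[1]))
      for (rest in enumerate_row(total - v, caps[-1]))
        out[[length(out) + 1]] <- c(v, rest)
    out
  }
  fill(list(), 1)
  lp_obs <- log_prob(tab)
  lps <- vapply(tables, log_prob, numeric(1))
  sum(exp(lps[lps <= lp_obs + 1e-7]))
}

# hand product-limit estimator at each distinct event time
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1; out <- numeric(0)
  for (t in ts) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  data.frame(time = ts, surv = out)
}

# Efron-tie-corrected Cox partial log-likelihood and gradient
oracle_efron_loglik <- function(beta, times, events, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    dset <- which(times == t & events == 1)
    rset <- which(times >= t)
    d <- length(dset)
    ll <- ll + sum(eta[dset])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum(w[rset]) - (l / d) * sum(w[dset]))
  }
  ll
}

oracle_efron_gradient <- function(beta, times, events, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  g <- numeric(ncol(x))
  for (t in sort(unique(times[events == 1]))) {
    dset <- which(times == t & events == 1)
    rset <- which(times >= t)
    d <- length(dset)
    g <- g + colSums(x[dset, , drop = FALSE])
    sw_r <- sum(w[rset]); sw_d <- sum(w[dset])
    sx_r <- colSums(x[rset, , drop = FALSE] * w[rset])
    sx_d <- colSums(x[dset, , drop = FALSE] * w[dset])
    for (l in seq_len(d) - 1)
      g <- g - (sx_r - (l / d) * sx_d) / (sw_r - (l / d) * sw_d)
  }
  g
}

# grid-search maximization of the Efron partial likelihood for a single
# covariate
oracle_cox_grid <- function(times, events, x, grid = seq(-5, 5, 5e-4)) {
  ll <- vapply(grid, oracle_efron_loglik, numeric(1),
               times = times, events = events, x = cbind(x))
  grid[which.max(ll)]
}

# two-group log-rank chi-square by direct tabulation over event times
oracle_logrank2 <- function(times, events, grp) {
  g1 <- sort(unique(grp))[1]
  u <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & grp == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == g1)
    u <- u + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}

# Wilcoxon signed-rank statistic with midranks, computed directly
oracle_signed_rank_stat <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# midrank Spearman rho via Pearson correlation of average ranks
oracle_spearman_midrank <- function(x, y) {
  stats::cor(rank(x), rank(y))
}
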