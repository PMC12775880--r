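# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, direct arithmetic, exhaustive search) kept
# separate from the package's own computation paths.

# Exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
# arrangements (no ties assumed).
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx_sets <- utils::combn(n1 + n2, n1, simplify = FALSE)
  us <- vapply(idx_sets, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2, 0)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# patterns (no ties in |d|, no zeros assumed).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# One-way ANOVA F computed from first principles (direct sums of squares).
oracle_anova_f <- function(groups) {
  n <- lengths(groups)
  allv <- unlist(groups)
  grand <- mean(allv)
  ssb <- sum(n * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  k <- length(groups); N <- sum(n)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Minimum number of letters: brute-force cover of the non-significance
# graph by maximal cliques (minimality over maximal cliques is exact for
# the edge-plus-vertex cover problem).
oracle_min_letters <- function(k, sig_matrix) {
  nonsig <- !sig_matrix; diag(nonsig) <- FALSE
  verts <- seq_len(k)
  subsets <- lapply(seq_len(2^k - 1),
                    function(m) verts[bitwAnd(m, 2^(verts - 1)) > 0])
  is_clique <- vapply(subsets, function(s) {
    if (length(s) <= 1) return(TRUE)
    all(nonsig[t(utils::combn(s, 2))])
  }, TRUE)
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i)
    !any(vapply(seq_along(cliques), function(j)
      j != i && length(cliques[[i]]) < length(cliques[[j]]) &&
        all(cliques[[i]] %in% cliques[[j]]), TRUE)), TRUE)]
  edges <- which(upper.tri(nonsig) & nonsig, arr.ind = TRUE)
  for (sz in seq_along(maximal)) {
    for (cc in utils::combn(length(maximal), sz, simplify = FALSE)) {
      cls <- maximal[cc]
      cov_v <- all(verts %in% unlist(cls))
      cov_e <- nrow(edges) == 0 ||
        all(apply(edges, 1, function(e)
          any(vapply(cls, function(cl) all(e %in% cl), TRUE))))
      if (cov_v && cov_e) return(sz)
    }
  }
  length(maximal)
}

n_letters <- function(assign) {
  length(unique(unlist(strsplit(paste(assign$letters, collapse = ""), ""))))
}

# Grid-search Box-Cox exponent maximizing the profile log-likelihood.
oracle_boxcox_grid <- function(x, grid = seq(-5, 5, by = 0.001)) {
  n <- length(x); slog <- sum(log(x))
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-10) log(x) else (x^l - 1) / l
    s2 <- mean((y - mean(y))^2)
    -(n / 2) * log(s2) + (l - 1) * slog
  }, 0)
  grid[which.max(ll)]
}

# Quick dataset builder for engine/reporting tests.
make_ds <- function(values_by_group, subject = NULL, factor2 = NULL) {
  df <- data.frame(
    group = rep(names(values_by_group), lengths(values_by_group)),
    value = unlist(values_by_group, use.names = FALSE))
  if (!is.null(subject)) df$subject <- subject
  if (!is.null(factor2)) df$factor2 <- factor2
  statpilot:::new_dataset(df)
}
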